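## Permutation-based relative variable importance: randomize one covariate,
## correlate the perturbed predictions with the originals, and score each
## variable by one minus the mean correlation, standardized to sum to one.

#' Permutation variable importance for a habitat-selection GAM
#'
#' For each covariate, its column in the model frame is permuted `n_reps`
#' times; each time the model predicts on the permuted frame and the
#' Pearson correlation with the original predictions is recorded. Raw
#' importance is `1 - mean(correlation)`; standardized importances are the
#' raw values rescaled to sum to one. The model is not refitted by default
#' (`refit = TRUE` refits on the permuted frame instead, a slower variant
#' of the same idea). Correlations are computed on the response
#' (probability) scale unless `scale = "link"`.
#'
#' @param fit a `habitat_gam`.
#' @param frame the model frame the fit was built from.
#' @param n_reps permutations per variable (default 100).
#' @param seed integer seed.
#' @param refit refit the model after each permutation instead of predicting
#'   through the original fit?
#' @param scale `"response"` or `"link"`.
#' @return data.frame of class `importance_table` with `variable`, `raw`,
#'   `standardized`, plus attributes `n_reps`, `seed`, `refit`, `scale`.
#' @export
permutation_importance <- function(fit, frame, n_reps = 100, seed = 1L,
                                   refit = FALSE,
                                   scale = c("response", "link")) {
  scale <- match.arg(scale)
  vars <- c(fit$smooth_vars, fit$linear_vars)
  set.seed(derive_seed(seed, "importance"))
  base <- as.numeric(stats::predict(fit$gam, newdata = frame, type = scale))
  n <- nrow(frame)
  raw <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    rs <- numeric(n_reps)
    for (rep in seq_len(n_reps)) {
      fperm <- frame
      fperm[[v]] <- fperm[[v]][sample.int(n)]
      pred <- if (refit) {
        refitted <- fit_habitat_gam(fperm, method = fit$gam$method %||% "REML")
        as.numeric(stats::predict(refitted$gam, newdata = fperm, type = scale))
      } else {
        as.numeric(stats::predict(fit$gam, newdata = fperm, type = scale))
      }
      if (stats::sd(pred) == 0 || stats::sd(base) == 0) {
        ## correlation undefined for constant predictions: no measurable
        ## contribution from this variable
        rs[rep] <- 1
      } else {
        rs[rep] <- stats::cor(base, pred)
      }
    }
    raw[v] <- 1 - mean(rs)
  }
  raw[abs(raw) < .Machine$double.eps^0.5 & raw < 0] <- 0
  std <- if (sum(raw) > 0) raw / sum(raw) else raw * 0
  out <- data.frame(variable = vars, raw = unname(raw),
                    standardized = unname(std))
  class(out) <- c("importance_table", "data.frame")
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "refit") <- refit
  attr(out, "scale") <- scale
  out
}

#' Bar chart of standardized variable importance
#'
#' @param x an `importance_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.importance_table <- function(x, ...) {
  ord <- order(x$standardized, decreasing = TRUE)
  graphics::barplot(100 * x$standardized[ord], names.arg = x$variable[ord],
                    ylab = "Relative importance (%)", las = 2, ...)
  invisible(x)
}
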