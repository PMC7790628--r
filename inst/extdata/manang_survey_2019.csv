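season,n_transects,total_length_km,individuals_1000m,individuals_1500m,visible_area_1000m_km2,visible_area_1500m_km2
spring,60,127.9,1387,1408,180,234
autumn,61,134.7,1419,1606,NA,234
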