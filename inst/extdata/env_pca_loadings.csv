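"variable","PC1","PC2","PC3","PC4"
"annual_mean_temp",0.956,0.014,-0.139,0.153
"mean_diurnal_range",0.68,-0.365,-0.026,-0.383
"temp_seasonality",-0.257,0.016,0.465,0.642
"max_temp_warmest_month",0.966,-0.046,-0.122,0.121
"min_temp_coldest_month",0.93,0.05,-0.153,0.201
"annual_precip",0.382,-0.395,0.777,-0.101
"precip_warmest_quarter",0.219,0.156,0.709,0.234
"precip_coldest_quarter",0.428,-0.605,0.21,-0.268
"gpp",0.377,0.839,0.128,-0.185
"lai",0.469,0.797,0.146,-0.125
"ndvi",0.339,-0.229,-0.378,0.611
"Eigenvalue",4.096,2.074,1.606,1.198
"Cumulative_variance_pct",37.23,56.09,70.69,81.58
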