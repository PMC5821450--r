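variable,fit_type,A_const,A_slope_log10m,A_intercept,B_const,B_slope_log10m,B_intercept,C,footnote
beta,powerI,0.5278,NA,NA,-0.3651,NA,NA,NA,1
t_stance_star,powerI,NA,-0.1841,1.4265,NA,-0.0725,-0.8266,NA,
S_star,linear,NA,-0.2226,1.4957,NA,-0.1058,1.2004,NA,
fx_peak_pos,linear,0.0862,NA,NA,0.1341,NA,NA,NA,1
fx_peak_neg,linear,-0.1686,NA,NA,-0.1550,NA,NA,NA,1
fz_peak,linear,0.8530,NA,NA,0.8848,NA,NA,NA,1
fz_mean,linear,0.3551,NA,NA,0.5775,NA,NA,NA,1
fnet_peak,linear,0.7979,NA,NA,0.8684,NA,NA,NA,1
t_fx_peak_pos,powerI,0.6675,NA,NA,-0.1011,NA,NA,NA,1
t_fx_peak_neg,linear,-0.0123,NA,NA,0.1794,NA,NA,NA,1
t_fx_zero,powerI,NA,0.0391,0.3939,-0.0705,NA,NA,NA,3
fz_at_fx_zero,linear,1.0326,NA,NA,0.5055,NA,NA,NA,2
fx_ms,linear,0.0821,NA,NA,0.0099,NA,NA,NA,1
fz_ms,linear,0.8300,NA,NA,0.5230,NA,NA,NA,2
fnet_ms,linear,0.8407,NA,NA,0.5234,NA,NA,NA,2
Xa2,powerII,-0.0082,NA,NA,3.0997,NA,NA,-0.165,1
Xa3,linear,-0.0593,NA,NA,-0.0289,NA,NA,NA,1
Xa4,linear,-0.0044,NA,NA,-0.0275,NA,NA,NA,1
Xa5,linear,-0.0008,NA,NA,-0.0327,NA,NA,NA,1
Za1,linear,0.5897,NA,NA,0.8725,NA,NA,NA,1
Za2,powerII,0.8899,NA,NA,0.4370,NA,NA,-0.532,1
Za3,linear,-0.2162,NA,NA,0.3127,NA,NA,NA,2
Za4,linear,-0.0693,NA,NA,0.1401,NA,NA,NA,1
Za5,linear,0.0033,NA,NA,-0.0456,NA,NA,NA,1
Za6,linear,-0.0264,NA,NA,0.0225,NA,NA,NA,1
nvd_star,powerI,0.0560,NA,NA,0.4764,NA,NA,NA,1
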