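region,class,extent_1985,extent_1985_ci,extent_2023,extent_2023_ci,trend,trend_lo,trend_hi,strength,strength_lo,strength_hi
pacific,tidal_marsh,277,12,308,13,1.23,1.13,1.31,NA,NA,NA
pacific,mangrove,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
pacific,tidal_flat,471,16,473,16,0.20,0.09,0.27,0.02,0.00,0.03
pacific,total,748,28,781,29,1.40,1.22,1.50,NA,NA,NA
atlantic,tidal_marsh,7195,301,7061,296,-2.75,-3.54,-2.11,-0.37,-0.44,-0.29
atlantic,mangrove,81,11,153,20,1.67,1.50,1.84,NA,NA,NA
atlantic,tidal_flat,411,14,347,12,-1.83,-1.90,-1.78,NA,NA,NA
atlantic,total,7687,326,7561,328,-3.35,-3.93,-2.62,-0.40,-0.44,-0.36
gulf,tidal_marsh,10214,428,8749,366,-37.65,-39.74,-35.64,NA,NA,NA
gulf,mangrove,2384,318,2281,304,-1.33,-2.43,-0.05,NA,NA,NA
gulf,tidal_flat,538,18,559,19,0.67,0.38,1.03,-0.23,-0.25,-0.19
gulf,total,13136,764,11589,689,-38.92,-41.49,-36.02,NA,NA,NA
conus,tidal_marsh,17686,740,16119,675,-39.13,-41.44,-37.69,-0.58,-0.81,-0.27
conus,mangrove,2464,329,2434,325,NA,NA,NA,NA,NA,NA
conus,tidal_flat,1420,48,1378,46,-0.70,-1.03,-0.38,-0.19,-0.21,-0.16
conus,total,21571,1118,19931,1046,-40.53,-43.40,-37.76,-0.73,-1.55,-0.06
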