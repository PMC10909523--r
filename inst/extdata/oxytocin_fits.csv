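cell,I_re,k_HAP,lambda_HAP,k_DAP,lambda_DAP,k_AHP,lambda_AHP
n130211,375,48.39,6.1,NA,NA,0.34,545
n130212-2,484,63.47,5.2,4.30,21.0,0.09,1329
n130214-2,486,48.35,6.8,4.10,28.2,0.58,468
n130215,350,30.26,7.5,5.00,31.3,0.31,337
n140924,281,10.11,15.9,NA,NA,NA,NA
n141002,341,88.51,5.4,0.60,61.3,NA,NA
n141021-2,466,39.62,6.5,5.88,37.3,1.13,482
n141022-5,472,44.16,5.2,3.77,20.1,1.01,357
LP181212,268,19.61,11.9,4.14,43.1,NA,NA
LP181219,357,51.93,7.2,NA,NA,0.39,702
LP181220,367,58.16,7.7,NA,NA,1.08,632
LP181221,383,48.75,9.7,3.24,74.1,0.61,659
LP190109,360,11.64,15.6,NA,NA,0.24,561
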