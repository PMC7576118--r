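stratum,period,census_N,ci_low,N_hat,ci_high,cv
rams,fall,25,6.45,21.41,71.11,0.75
ewes,fall,28,10.32,24.28,57.54,0.53
adults,fall,53,24.59,54.91,122.61,0.47
rams,spring,30,10.29,27.37,72.79,0.59
ewes,spring,39,6.76,24.24,87.72,0.70
adults,spring,69,32.15,65.96,135.30,0.42
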