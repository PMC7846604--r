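year,mu_log,sd_log
2011,7.72,0.166
2016,8.16,0.132
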