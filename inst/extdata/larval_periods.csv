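temperature,mean_larval_days
21,20.79
24,12.86
27,12.47
30,11.42
33,8.47
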