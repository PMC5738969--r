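model,lower,mean,upper
model1,12091788,NA,15041447
model2,12517841,13688669,14922332
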