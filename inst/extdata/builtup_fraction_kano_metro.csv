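year,pct_builtup
1986,13.85
2000,17.38
2005,19.34
2006,19.61
2014,27.81
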