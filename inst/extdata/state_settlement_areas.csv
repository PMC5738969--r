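state,total_area_km2,settlement_area_km2
Kaduna,46053,423.3
Kano,20131,541.7
Total,66184,965.0
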