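roi_id,type,settled_area_ha,phi
rijiyar_lemo,B,37.826,2.25
rijiyar_lemo,D,2.899,3.53
rijiyar_lemo,E,40.890,1.22
rijiyar_lemo,M,1.0745,2.95
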