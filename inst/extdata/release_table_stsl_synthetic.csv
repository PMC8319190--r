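temperature_C,t_rel_s
40.0,2300
40.5,900
41.0,350
41.5,140
42.0,63.0
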