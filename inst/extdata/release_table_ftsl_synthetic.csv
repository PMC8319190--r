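temperature_C,t_rel_s
40.0,300
40.5,120
41.0,45
41.5,18
42.0,8.2
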