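date,field,mean_height_mm
2024-04-08,A1,192
2024-06-03,A1,212
2024-04-08,A2,191
2024-06-03,A2,174
2024-04-08,E1,188
2024-06-03,E1,175
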