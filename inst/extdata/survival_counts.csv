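date,field,survival_count
2024-04-22,A1,10
2024-04-29,A1,27
2024-05-06,A1,31
2024-05-13,A1,33
2024-05-20,A1,42
2024-05-27,A1,51
2024-04-22,A2,23
2024-04-29,A2,21
2024-05-06,A2,29
2024-05-13,A2,30
2024-05-20,A2,33
2024-05-27,A2,36
2024-04-22,E1,12
2024-04-29,E1,12
2024-05-06,E1,14
2024-05-13,E1,15
2024-05-20,E1,16
2024-05-27,E1,18
2024-04-22,E2,24
2024-04-29,E2,22
2024-05-06,E2,27
2024-05-13,E2,31
2024-05-20,E2,34
2024-05-27,E2,36
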