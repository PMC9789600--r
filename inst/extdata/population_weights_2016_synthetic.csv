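age_group,weight
1-4,6060000
5-9,7070000
10-14,5900000
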