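source_id,time_ms
0,446
1,355
2,53
2,258
2,300
2,424
2,457
3,88
3,466
4,100
4,212
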