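K,replicate,lnP
1,1,-4600
1,2,-4607
1,3,-4594
2,1,-4200
2,2,-4206
2,3,-4195
3,1,-3800
3,2,-3805
3,3,-3794
4,1,-3780
4,2,-3786
4,3,-3775
5,1,-3760
5,2,-3765
5,3,-3754
6,1,-3740
6,2,-3747
6,3,-3735
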