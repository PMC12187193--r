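as_16,as_10,as_high,score_16,score_10,score_high,total,phenotype
1,2,3,1,1,1,3,low
3,4,5.5,3,3,4,10,high
1.75,2.59,3.35,2,2,2,6,intermediate
2.6,3.68,4.2,3,3,3,9,intermediate
3.45,4.77,5.05,4,4,4,12,high
3,2,3,3,1,1,5,low
4,5,5.5,4,4,4,12,high
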