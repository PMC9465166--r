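id,antecedent,support_pct,confidence_pct,lift
1,sweet|kidney,10.59,69.23,1.44
2,sweet|warm,6.67,73.91,1.53
3,sour,5.88,71.43,1.48
4,sweet|liver|kidney,5.49,66.67,1.38
5,sweet|stomach,6.67,65.38,1.36
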