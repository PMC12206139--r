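mouse,stage,separated,density,radius_um,tortuosity
1,normal,FALSE,0.0956,2.4781,0.5573
1,normal,TRUE,0.0941,3.2731,0.5375
2,normal,FALSE,0.0961,2.5345,0.5495
2,normal,TRUE,0.0945,3.2699,0.5313
3,normal,FALSE,0.0953,2.4063,0.5534
3,normal,TRUE,0.0938,3.1215,0.5349
1,early,FALSE,0.1078,2.5064,0.5519
1,early,TRUE,0.0552,2.6495,0.4822
2,early,FALSE,0.0931,2.5129,0.5791
2,early,TRUE,0.0541,2.6995,0.4978
3,early,FALSE,0.1005,2.5097,0.5455
3,early,TRUE,0.0515,2.6345,0.4884
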