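task,age_low,age_high,mean,sd
encoding,16,29,52,9
encoding,30,44,49,9.5
encoding,45,59,45,10
encoding,60,75,41,10
retrieval,16,29,11,2.2
retrieval,30,44,10.5,2.3
retrieval,45,59,9.8,2.5
retrieval,60,75,9,2.6
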