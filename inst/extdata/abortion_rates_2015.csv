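level,name,rate_per_1000
national,India,47
state,Assam,70
state,Tamil Nadu,37
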