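id,target,spf,name
s1,80,100,s1
s2,80,100,s2
s3,80,100,s3
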