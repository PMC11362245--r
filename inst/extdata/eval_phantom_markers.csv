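marker,x,y,z
A,55.39,99.97,-1008.40
B,55.28,80.19,-1008.90
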