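scale,loading,eigenvalue
fl,0.475,2.62
pd,-0.502,0.92
wr,-0.475,0.55
sa,-0.392,0.48
ls,0.378,0.42
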