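line,target,size_delta,freq_pct,overall_pct
N8a,sgRNA134,1,64.2,100.0
N8a,sgRNA134,2,7.3,100.0
N8a,sgRNA134,-2,9.0,100.0
N8a,sgRNA134,-10,7.9,100.0
N8a,sgRNA134,-28,11.6,100.0
T205,sgRNA73,1,59.1,71.7
T205,sgRNA73,4,12.6,71.7
T81,sgRNA73,1,31.7,44.5
T81,sgRNA73,-11,12.8,44.5
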