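line,target,wt_size_bp,size_delta,freq_pct,overall_pct
N11a,sgRNA668,206,1,25.2,43.4
N11a,sgRNA668,206,-1,4.4,43.4
N11a,sgRNA668,206,-7,13.8,43.4
T205,sgRNA73,227,1,50.4,63.6
T205,sgRNA73,227,4,13.2,63.6
T77,sgRNA73,227,1,7.9,14.7
T77,sgRNA73,227,-2,6.8,14.7
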