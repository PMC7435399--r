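"donor","acceptor","intramolecular","timestep","r_cut","n_frames"
4,3,FALSE,0.5,300,2000
6,5,FALSE,0.5,300,2000
14,13,FALSE,0.5,300,2000
16,15,FALSE,0.5,300,2000
26,25,FALSE,0.5,300,2000
28,27,FALSE,0.5,300,2000
34,33,FALSE,0.5,300,2000
38,37,FALSE,0.5,300,2000
40,39,FALSE,0.5,300,2000
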