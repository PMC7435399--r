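{"tau_ps":88.3640030280512,"unresolved":false,"tail_rate":0.0194454908492056,"tail_r2":0.837816805361701,"near_window_limit":false}
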