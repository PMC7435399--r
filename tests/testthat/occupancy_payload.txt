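516 18 958 245 263
293 292 1415
705 523 55 305 391 21
1410 244 346
1032 459 509
1150 10 27 84 494 74 161
1950 50
1023 283 85 131 478
1050 89 861
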