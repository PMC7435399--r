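"r_pm","g"
15,0
45,0
75,0
105,0
135,0
165,0
195,0
225,0
255,73.7474947774919
285,0
315,0
345,0
375,0
405,0
435,0
465,0
495,257.466940605987
525,0
555,0
585,0
615,0
645,0
675,0
705,0
735,0
765,0
795,0
825,0
855,0
885,0
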