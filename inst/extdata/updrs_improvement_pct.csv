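patient,improvement_pct
1,59.0
2,41.7
3,46.2
4,61.0
5,23.1
6,43.2
7,67.4
8,25.8
9,47.2
10,59.3
11,85.7
12,67.3
13,68.5
14,52.8
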