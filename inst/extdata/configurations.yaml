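# Reward-configuration registry: label -> four baited hole indices
# (0-based, row-major, row 0 nearest the north entrance).
A: [1, 4, 10, 15]
B: [2, 7, 8, 13]
C: [0, 5, 11, 14]
D: [3, 6, 9, 12]
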