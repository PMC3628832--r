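# Synthetic disordered-like reference composition (20 lines: residue fraction).
# Constructed from average proteome frequencies with an
# disorder-promoting bias; a stand-in for a curated reference set.
A 0.10878759
C 0.00735104
D 0.07191044
E 0.08890027
F 0.02071169
G 0.09311480
H 0.01218019
I 0.03197971
K 0.07691520
L 0.05183288
M 0.01298505
N 0.02178483
P 0.06190093
Q 0.05175971
R 0.07283237
S 0.08639789
T 0.07032999
V 0.03686252
W 0.00579498
Y 0.01566791
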