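# Synthetic ordered-like reference composition (20 lines: residue fraction).
# Constructed from average proteome frequencies with an
# order-promoting bias; a stand-in for a curated reference set.
A 0.06244047
C 0.01864143
D 0.04127421
E 0.05102581
F 0.05252256
G 0.05344481
H 0.03088762
I 0.08109702
K 0.04414677
L 0.13144248
M 0.03292865
N 0.05524394
P 0.03552908
Q 0.02970836
R 0.04180337
S 0.04958953
T 0.04036708
V 0.09347928
W 0.01469543
Y 0.03973210
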