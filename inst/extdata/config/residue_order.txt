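# Display order for composition profiles: residues ranked by increasing
# disorder-promoting potential (TOP-IDP ordering); one residue per line.
W
F
Y
I
M
L
V
N
C
T
A
G
R
D
H
Q
S
K
E
P
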