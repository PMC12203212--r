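# Synthetic 3Di substitution matrix (match/mismatch log-odds style).
# Not Foldseek's published 3Di matrix: a flat +6 match / -4 mismatch model
# over the 20-letter 3Di alphabet, matching a uniform-substitution process.
    A  C  D  E  F  G  H  I  K  L  M  N  P  Q  R  S  T  V  W  Y
A   6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
C  -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
D  -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
E  -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
F  -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
G  -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
H  -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
I  -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
K  -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
L  -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4
M  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4 -4
N  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4 -4
P  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4 -4
Q  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4 -4
R  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4 -4
S  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4 -4
T  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4 -4
V  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4 -4
W  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6 -4
Y  -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4 -4  6
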