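residue,total,side_chain
A,129,67
R,274,196
N,195,113
D,193,106
C,167,104
E,223,138
Q,225,144
G,104,NA
H,224,151
I,197,140
L,201,137
K,236,167
M,224,160
F,240,175
P,159,105
S,155,80
T,172,102
W,285,217
Y,263,187
V,174,117
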