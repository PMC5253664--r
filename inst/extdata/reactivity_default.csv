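residue,reactivity
C,3500
W,1300
Y,1300
M,850
F,690
H,480
R,350
I,180
L,170
V,85
P,65
Q,54
T,51
K,35
S,32
E,23
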