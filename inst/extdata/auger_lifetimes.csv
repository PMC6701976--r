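# K-shell core-hole 1/e lifetimes (fs), from measured K-level natural widths
# (Krause & Oliver, J. Phys. Chem. Ref. Data 8, 329 (1979); tau = hbar/Gamma).
# H has a single shell and no Auger channel (NA).
element,lifetime_fs
H,NA
C,10.7
N,7.1
O,4.9
S,1.3
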