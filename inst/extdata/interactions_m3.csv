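# Synthetic Martini-3-style bead-pair Lennard-Jones minima (epsilon kJ/mol, sigma nm)
typeA,typeB,epsilon,sigma
W,W,5.000,0.470
W,P5,5.600,0.470
W,P4,5.000,0.470
W,P3,5.000,0.470
W,P1,4.500,0.470
W,Nda,4.500,0.470
W,Na,4.000,0.470
W,N0,3.500,0.470
W,C5,3.100,0.470
W,C3,2.700,0.470
W,C1,2.000,0.470
W,Qd,5.600,0.470
W,Qa,5.600,0.470
P5,P5,5.600,0.470
P5,P4,5.600,0.470
P5,P3,5.600,0.470
P5,P1,5.000,0.470
P5,Nda,5.000,0.470
P5,Na,4.500,0.470
P5,N0,4.000,0.470
P5,C5,3.100,0.470
P5,C3,2.700,0.470
P5,C1,2.000,0.470
P5,Qd,5.600,0.470
P5,Qa,5.600,0.470
P4,P4,5.000,0.470
P4,P3,5.000,0.470
P4,P1,4.500,0.470
P4,Nda,4.500,0.470
P4,Na,4.000,0.470
P4,N0,3.500,0.470
P4,C5,3.100,0.470
P4,C3,2.700,0.470
P4,C1,2.000,0.470
P4,Qd,5.000,0.470
P4,Qa,5.000,0.470
P3,P3,5.000,0.470
P3,P1,4.500,0.470
P3,Nda,4.500,0.470
P3,Na,4.000,0.470
P3,N0,3.500,0.470
P3,C5,3.100,0.470
P3,C3,3.100,0.470
P3,C1,2.300,0.470
P3,Qd,5.000,0.470
P3,Qa,5.000,0.470
P1,P1,4.500,0.470
P1,Nda,4.500,0.470
P1,Na,4.500,0.470
P1,N0,4.000,0.470
P1,C5,3.500,0.470
P1,C3,3.100,0.470
P1,C1,2.700,0.470
P1,Qd,4.500,0.470
P1,Qa,4.500,0.470
Nda,Nda,4.500,0.470
Nda,Na,4.000,0.470
Nda,N0,3.500,0.470
Nda,C5,3.500,0.470
Nda,C3,3.100,0.470
Nda,C1,2.700,0.470
Nda,Qd,5.000,0.470
Nda,Qa,5.000,0.470
Na,Na,4.000,0.470
Na,N0,3.500,0.470
Na,C5,3.500,0.470
Na,C3,3.500,0.470
Na,C1,3.100,0.470
Na,Qd,4.500,0.470
Na,Qa,4.500,0.470
N0,N0,3.500,0.470
N0,C5,3.500,0.470
N0,C3,3.500,0.470
N0,C1,3.500,0.470
N0,Qd,3.500,0.470
N0,Qa,3.500,0.470
C5,C5,3.500,0.470
C5,C3,3.500,0.470
C5,C1,3.500,0.470
C5,Qd,3.100,0.470
C5,Qa,3.100,0.470
C3,C3,3.500,0.470
C3,C1,3.500,0.470
C3,Qd,2.700,0.470
C3,Qa,2.700,0.470
C1,C1,3.500,0.470
C1,Qd,2.000,0.470
C1,Qa,2.000,0.470
Qd,Qd,5.600,0.470
Qd,Qa,5.600,0.470
Qa,Qa,5.600,0.470
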