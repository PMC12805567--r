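# Synthetic Martini-2-style bead-pair table used for the peptidoglycan-layer field
typeA,typeB,epsilon,sigma
W,W,4.750,0.470
W,P5,5.320,0.470
W,P4,4.750,0.470
W,P3,4.750,0.470
W,P1,4.275,0.470
W,Nda,4.275,0.470
W,Na,3.800,0.470
W,N0,3.325,0.470
W,C5,2.945,0.470
W,C3,2.565,0.470
W,C1,1.900,0.470
W,Qd,5.320,0.470
W,Qa,5.320,0.470
P5,P5,5.320,0.470
P5,P4,5.320,0.470
P5,P3,5.320,0.470
P5,P1,4.750,0.470
P5,Nda,4.750,0.470
P5,Na,4.275,0.470
P5,N0,3.800,0.470
P5,C5,2.945,0.470
P5,C3,2.565,0.470
P5,C1,1.900,0.470
P5,Qd,5.320,0.470
P5,Qa,5.320,0.470
P4,P4,4.750,0.470
P4,P3,4.750,0.470
P4,P1,4.275,0.470
P4,Nda,4.275,0.470
P4,Na,3.800,0.470
P4,N0,3.325,0.470
P4,C5,2.945,0.470
P4,C3,2.565,0.470
P4,C1,1.900,0.470
P4,Qd,4.750,0.470
P4,Qa,4.750,0.470
P3,P3,4.750,0.470
P3,P1,4.275,0.470
P3,Nda,4.275,0.470
P3,Na,3.800,0.470
P3,N0,3.325,0.470
P3,C5,2.945,0.470
P3,C3,2.945,0.470
P3,C1,2.185,0.470
P3,Qd,4.750,0.470
P3,Qa,4.750,0.470
P1,P1,4.275,0.470
P1,Nda,4.275,0.470
P1,Na,4.275,0.470
P1,N0,3.800,0.470
P1,C5,3.325,0.470
P1,C3,2.945,0.470
P1,C1,2.565,0.470
P1,Qd,4.275,0.470
P1,Qa,4.275,0.470
Nda,Nda,4.275,0.470
Nda,Na,3.800,0.470
Nda,N0,3.325,0.470
Nda,C5,3.325,0.470
Nda,C3,2.945,0.470
Nda,C1,2.565,0.470
Nda,Qd,4.750,0.470
Nda,Qa,4.750,0.470
Na,Na,3.800,0.470
Na,N0,3.325,0.470
Na,C5,3.325,0.470
Na,C3,3.325,0.470
Na,C1,2.945,0.470
Na,Qd,4.275,0.470
Na,Qa,4.275,0.470
N0,N0,3.325,0.470
N0,C5,3.325,0.470
N0,C3,3.325,0.470
N0,C1,3.325,0.470
N0,Qd,3.325,0.470
N0,Qa,3.325,0.470
C5,C5,3.325,0.470
C5,C3,3.325,0.470
C5,C1,3.325,0.470
C5,Qd,2.945,0.470
C5,Qa,2.945,0.470
C3,C3,3.325,0.470
C3,C1,3.325,0.470
C3,Qd,2.565,0.470
C3,Qa,2.565,0.470
C1,C1,3.325,0.470
C1,Qd,1.900,0.470
C1,Qa,1.900,0.470
Qd,Qd,5.320,0.470
Qd,Qa,5.320,0.470
Qa,Qa,5.320,0.470
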