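i,j
Fp1,Fpz
Fp1,AF7
Fp1,AF3
Fpz,Fp2
Fpz,AF3
Fpz,AF4
Fp2,AF4
Fp2,AF8
F7,FC5
F7,AF7
F7,F5
F7,FT7
F3,FC5
F3,FC1
F3,AF7
F3,AF3
F3,F5
F3,F1
F3,FC3
Fz,FC2
Fz,AF3
Fz,AF4
Fz,F1
Fz,F2
Fz,FCz
F4,FC2
F4,AF4
F4,AF8
F4,F2
F4,F6
F4,FC4
F8,FC6
F8,AF8
F8,F6
F8,FT8
FC5,T7
FC5,C3
FC5,F5
FC5,FC3
FC5,C5
FC5,FT7
FC1,C3
FC1,Cz
FC1,F1
FC1,FC3
FC1,FCz
FC1,C1
FC2,Cz
FC2,C4
FC2,F2
FC2,FCz
FC2,FC4
FC2,C2
FC6,C4
FC6,T8
FC6,F6
FC6,FC4
FC6,C6
FC6,FT8
T7,CP5
T7,C5
T7,FT7
T7,TP7
C3,CP5
C3,CP1
C3,FC3
C3,C5
C3,C1
C3,CP3
Cz,CP1
Cz,CP2
Cz,Pz
Cz,FCz
Cz,C1
Cz,C2
C4,CP2
C4,CP6
C4,FC4
C4,C2
C4,C6
C4,CP4
T8,CP6
T8,C6
T8,FT8
T8,TP8
CP5,P7
CP5,P3
CP5,C5
CP5,CP3
CP5,P5
CP5,TP7
CP1,CP2
CP1,P3
CP1,Pz
CP1,C1
CP1,CP3
CP1,P1
CP2,Pz
CP2,P4
CP2,C2
CP2,CP4
CP2,P2
CP6,P4
CP6,P8
CP6,C6
CP6,CP4
CP6,P6
CP6,TP8
P7,P5
P7,PO5
P7,TP7
P7,PO7
P3,CP3
P3,P5
P3,P1
P3,PO5
P3,PO3
Pz,POz
Pz,P1
Pz,P2
P4,CP4
P4,P2
P4,P6
P4,PO4
P4,PO6
P8,P6
P8,PO6
P8,TP8
P8,PO8
POz,O1
POz,O2
POz,P1
POz,P2
POz,PO3
POz,PO4
POz,Oz
O1,O2
O1,P1
O1,PO5
O1,PO3
O1,PO7
O1,Oz
O2,PO4
O2,PO6
O2,PO8
O2,Oz
AF7,AF3
AF7,F5
AF3,F5
AF3,F1
AF4,AF8
AF4,F2
AF4,F6
AF8,F6
F5,FC3
F1,FC3
F1,FCz
F2,FCz
F2,FC4
F6,FC4
F6,FT8
FC3,C5
FC3,C1
FCz,C1
FCz,C2
FC4,C2
FC4,C6
C5,CP3
C5,FT7
C5,TP7
C1,CP3
C2,CP4
C6,CP4
C6,FT8
C6,TP8
CP3,P5
CP3,P1
CP4,P2
CP4,P6
P5,PO5
P5,PO3
P5,TP7
P5,PO7
P1,PO3
P2,PO4
P6,PO4
P6,PO6
P6,TP8
P6,PO8
PO5,PO3
PO5,PO7
PO3,Oz
PO4,PO6
PO4,Oz
PO6,PO8
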