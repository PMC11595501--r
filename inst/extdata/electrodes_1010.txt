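label	inclination_deg	azimuth_deg
AF3	78.187886	108.736543
AF4	78.187886	71.263457
AF7	90	126
AF8	90	54
AFz	67.5	90
C1	22.5	180
C2	22.5	0
C3	45	180
C4	45	0
C5	67.5	180
C6	67.5	0
CP1	34.454147	-126.958414
CP2	34.454147	-53.041586
CP3	51.846221	-143.971722
CP4	51.846221	-36.028278
CP5	70.705315	-154.072787
CP6	70.705315	-25.927213
CPz	22.5	-90
Cz	0	0
F1	54.023095	108.035268
F2	54.023095	71.964732
F3	65.150369	121.996138
F4	65.150369	58.003862
F5	77.350516	133.538751
F6	77.350516	46.461249
F7	90	144
F8	90	36
FC1	34.454147	126.958414
FC2	34.454147	53.041586
FC3	51.846221	143.971722
FC4	51.846221	36.028278
FC5	70.705315	154.072787
FC6	70.705315	25.927213
FCz	22.5	90
Fp1	90	108
Fp2	90	72
Fpz	90	90
FT7	90	162
FT8	90	18
Fz	45	90
O1	90	-108
O2	90	-72
Oz	90	-90
P1	54.023095	-108.035268
P2	54.023095	-71.964732
P3	65.150369	-121.996138
P4	65.150369	-58.003862
P5	77.350516	-133.538751
P6	77.350516	-46.461249
P7	90	-144
P8	90	-36
PO3	78.187886	-108.736543
PO4	78.187886	-71.263457
PO7	90	-126
PO8	90	-54
POz	67.5	-90
Pz	45	-90
T7	90	180
T8	90	0
TP7	90	-162
TP8	90	-18
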