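resname	chi1	chi2	chi3	chi4	prob
SER	-65	NA	NA	NA	0.45
SER	180	NA	NA	NA	0.3
SER	65	NA	NA	NA	0.25
CYS	-65	NA	NA	NA	0.5
CYS	180	NA	NA	NA	0.3
CYS	65	NA	NA	NA	0.2
THR	-60	NA	NA	NA	0.45
THR	60	NA	NA	NA	0.45
THR	180	NA	NA	NA	0.1
VAL	175	NA	NA	NA	0.6
VAL	-60	NA	NA	NA	0.25
VAL	65	NA	NA	NA	0.15
LEU	-65	175	NA	NA	0.6
LEU	175	65	NA	NA	0.3
LEU	-85	65	NA	NA	0.1
ILE	-65	170	NA	NA	0.6
ILE	-57	-60	NA	NA	0.2
ILE	62	170	NA	NA	0.2
MET	-65	180	75	NA	0.4
MET	-65	180	180	NA	0.3
MET	180	180	75	NA	0.3
PHE	-65	90	NA	NA	0.5
PHE	180	80	NA	NA	0.35
PHE	65	90	NA	NA	0.15
TYR	-65	90	NA	NA	0.5
TYR	180	80	NA	NA	0.35
TYR	65	90	NA	NA	0.15
TRP	-65	95	NA	NA	0.4
TRP	180	-105	NA	NA	0.3
TRP	65	-90	NA	NA	0.3
HIS	-65	-70	NA	NA	0.4
HIS	180	60	NA	NA	0.3
HIS	-65	80	NA	NA	0.3
ASP	-70	-15	NA	NA	0.5
ASP	180	0	NA	NA	0.3
ASP	65	-15	NA	NA	0.2
ASN	-65	-20	NA	NA	0.45
ASN	180	30	NA	NA	0.3
ASN	65	-20	NA	NA	0.25
GLU	-65	180	-10	NA	0.4
GLU	180	180	0	NA	0.35
GLU	-65	-65	-40	NA	0.25
GLN	-65	180	0	NA	0.4
GLN	180	180	0	NA	0.35
GLN	-65	-65	-40	NA	0.25
LYS	-65	180	180	180	0.4
LYS	180	180	180	180	0.35
LYS	65	180	180	180	0.25
ARG	-65	180	180	85	0.4
ARG	180	180	180	180	0.35
ARG	65	180	180	-85	0.25
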