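residue	volume_nm3	hydrophilicity	group
G	0.0664	-0.4	Minuscule
A	0.0915	1.8	Minuscule
S	0.0991	-0.8	Minuscule
C	0.1056	2.5	Minuscule
T	0.1221	-0.7	Small
D	0.1245	-3.5	Small
P	0.1293	-1.6	Small
N	0.1352	-3.5	Small
V	0.1417	4.2	Small
E	0.1551	-3.5	Intermediate
Q	0.1611	-3.5	Intermediate
H	0.1673	-3.2	Intermediate
L	0.1679	3.8	Intermediate
I	0.1688	4.5	Intermediate
M	0.1708	1.9	Intermediate
K	0.1713	-3.9	Intermediate
R	0.2021	-4.5	Large
F	0.2034	2.8	Large
Y	0.2036	-1.3	Large
W	0.2376	-0.9	Large
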