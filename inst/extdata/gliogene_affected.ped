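A	A1	0	0	2	2	1	Oligodendroglioma	48
A	A2	0	0	1	2	1	Astrocytoma	33
A	A3	0	0	2	2	0	Ependymoma	20
B	B1	0	0	2	2	1	Astrocytoma	40
B	B2	0	0	2	2	1	Oligodendroglioma	30
C	C1	0	0	1	2	1	Anaplastic Astro	40
C	C2	0	0	1	2	1	GBM	46
C	C3	0	0	2	2	0	Astrocytoma	16
D	D1	D2	0	2	2	1	GBM	54
D	D2	0	0	1	2	0	UNK Glioma	31
D	D3	0	0	2	2	0	GBM	55
E	E1	0	0	1	2	1	Anaplastic Astro	39
E	E2	0	0	2	2	1	Oligodendroglioma	27
F	F1	0	0	1	2	1	GBM	61
F	F2	0	0	2	2	1	GBM	52
G	G1	G2	0	1	2	1	Anaplastic Oligo	28
G	G2	G3	0	1	2	1	Anaplastic Astro	29
G	G3	0	0	1	2	0	UNK Glioma	50
H	H1	0	0	1	2	1	GBM	59
H	H2	0	0	1	2	0	UNK Glioma	42
I	I1	0	0	2	2	1	Anaplastic Oligo	58
I	I2	0	0	1	2	1	Oligodendroglioma	32
J	J1	0	0	2	2	1	Anaplastic Astro	27
J	J2	0	0	1	2	1	Oligoastrocytoma	38
K	K1	0	0	1	2	0	Anaplastic Oligo	65
K	K2	0	0	2	2	1	GBM	82
K	K3	0	0	2	2	0	GBM	79
K	K4	0	0	2	2	0	Anaplastic Astro	81
K	K5	0	0	2	2	0	UNK Glioma	63
K	K6	0	0	1	2	0	GBM	61
L	L1	0	0	2	2	1	Astrocytoma	39
L	L2	0	0	2	2	1	GBM	66
M	M1	0	0	2	2	1	GBM	66
M	M2	0	0	2	2	0	GBM	59
N	N1	0	0	1	2	1	GBM	66
N	N2	0	0	1	2	0	GBM	53
O	O1	0	O2	2	2	1	Astrocytoma	43
O	O2	0	0	2	2	0	UNK Glioma	27
O	O3	0	O2	1	2	0	GBM	45
P	P1	0	0	1	2	1	Anaplastic Astro	28
P	P2	0	0	1	2	1	Oligoastrocytoma	18
Q	Q1	0	0	2	2	1	GBM	10
Q	Q2	0	0	2	2	0	GBM	65
R	R1	0	0	2	2	1	GBM	44
R	R2	0	0	1	2	0	GBM	22
R	R3	R2	0	2	2	1	Astrocytoma	24
R	R4	R2	0	2	2	0	Astrocytoma	4
R	R5	0	0	2	2	0	UNK Glioma	11
R	R6	0	0	2	2	1	Astrocytoma	38
R	R7	0	0	2	2	0	UNK Glioma	49
R	R8	0	0	2	2	0	UNK Glioma	46
R	R9	0	0	1	2	0	UNK Glioma	78
R	R10	0	0	1	2	0	UNK Glioma	4
S	S1	0	0	2	2	1	Oligodendroglioma	37
S	S2	0	0	1	2	1	Ana Oligoastro	41
T	T1	0	T2	2	2	1	GBM	68
T	T2	0	0	2	2	0	GBM	78
T	T3	0	0	1	2	0	UNK Glioma	49
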