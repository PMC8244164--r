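code_start	code_end	category
A00	B99	infectious diseases
C00	D49	neoplasms
D50	D89	hematopoietic
E00	E89	endocrine
F01	F99	mental health
G00	G99	neurological
H00	H59	sense organs
H60	H95	sense organs
I00	I99	circulatory
J00	J99	respiratory
K00	K95	digestive
L00	L99	dermatologic
M00	M99	musculoskeletal
N00	N99	genitourinary
O00	O99	gynecologic and obstetric
R00	R99	symptoms
S00	T88	injuries and poisonings
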