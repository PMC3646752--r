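aa	atp	nadph	note
A	1	1	alanine, textbook biosynthetic cost from glucose
R	7	4	arginine
N	3	1	asparagine
D	1	1	aspartate
C	4	5	cysteine, includes sulfate assimilation
Q	1	1	glutamine
E	1	1	glutamate
G	1	1	glycine
H	6	1	histidine
I	2	5	isoleucine
L	0	2	leucine
K	2	4	lysine
M	7	8	methionine, includes sulfate assimilation
F	1	2	phenylalanine
P	1	3	proline
S	1	1	serine
T	2	3	threonine
W	5	2	tryptophan
Y	1	2	tyrosine
V	2	2	valine
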