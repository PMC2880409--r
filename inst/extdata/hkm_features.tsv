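letter	H	K	M
A	1.80	0.000	71.03711
R	-4.50	12.480	156.10111
N	-3.50	0.000	114.04293
D	-3.50	3.650	115.02694
C	2.50	8.180	103.00919
Q	-3.50	0.000	128.05858
E	-3.50	4.250	129.04259
G	-0.40	0.000	57.02146
H	-3.20	6.000	137.05891
I	4.50	0.000	113.08406
L	3.80	0.000	113.08406
K	-3.90	10.530	128.09496
M	1.90	0.000	131.04049
F	2.80	0.000	147.06841
P	-1.60	0.000	97.05276
S	-0.80	0.000	87.03203
T	-0.70	0.000	101.04768
W	-0.90	0.000	186.07931
Y	-1.30	10.070	163.06333
V	4.20	0.000	99.06841
X	-0.49	2.758	118.80572
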