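# Four-state secondary-structure propensity table used by the built-in
# window-averaging predictor (a documented stand-in for database-trained
# tools such as SOPMA; see the methods vignette).
# helix/strand: Chou & Fasman (1978) P(alpha), P(beta) conformational
# propensities. coil: Chou & Fasman P(turn), read here as a general aperiodic
# propensity. turn: Chou & Fasman per-residue turn occurrence probabilities
# p(t), normalized to unit mean so all four columns share the scale
# "observed/expected under a uniform background".
aa	helix	strand	turn	coil
A	1.42	0.83	0.690	0.66
R	0.98	0.93	0.994	0.95
N	0.67	0.89	1.684	1.56
D	1.01	0.54	1.527	1.46
C	0.70	1.19	1.245	1.19
Q	1.11	1.10	1.025	0.98
E	1.51	0.37	0.774	0.74
G	0.57	0.75	1.632	1.56
H	1.00	0.87	0.994	0.95
I	1.08	1.60	0.492	0.47
L	1.21	1.30	0.617	0.59
K	1.16	0.74	1.056	1.01
M	1.45	1.05	0.628	0.60
F	1.13	1.38	0.617	0.60
P	0.57	0.55	1.067	1.52
S	0.77	0.75	1.255	1.43
T	0.83	1.19	0.900	0.96
W	1.08	1.37	1.004	0.96
Y	0.69	1.47	1.151	1.14
V	1.06	1.70	0.649	0.50
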