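# Bjellqvist et al. (1993, 1994) pKa set as used by Expasy ProtParam.
# group: side chain residue, Nterm/Cterm defaults, or residue-specific terminal
# overrides (Nterm_X / Cterm_X applied when the chain starts/ends with X).
group	sign	pka
Nterm	positive	7.5
Cterm	negative	3.55
K	positive	10.0
R	positive	12.0
H	positive	5.98
D	negative	4.05
E	negative	4.45
C	negative	9.0
Y	negative	10.0
Nterm_A	positive	7.59
Nterm_M	positive	7.0
Nterm_S	positive	6.93
Nterm_P	positive	8.36
Nterm_T	positive	6.82
Nterm_V	positive	7.44
Nterm_E	positive	7.7
Cterm_D	negative	4.55
Cterm_E	negative	4.75
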