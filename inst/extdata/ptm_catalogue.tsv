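# Starter modification catalogue; user-extensible via register_modification().
# columns: name	category	targets (comma list; N-term / C-term allowed)	formula	glycan
# exactly one of formula / glycan is non-empty per row
name	category	targets	formula	glycan
Acetyl	PTM	K,N-term	C2H2O	
Phospho	PTM	S,T,Y	HO3P	
Methyl	PTM	K,R	CH2	
Dimethyl	PTM	K,R	C2H4	
Trimethyl	PTM	K	C3H6	
Oxidation	PTM	M,W	O	
Deamidated	PTM	N,Q	H-1N-1O	
Formyl	PTM	K,N-term	CO	
Succinyl	PTM	K	C4H4O3	
GG	PTM	K	C4H6N2O2	
Myristoyl	PTM	G,K	C14H26O	
Carbamidomethyl	fixed	C	C2H3NO	
Carbamyl	fixed	K,N-term	CHNO	
G0	N-glycan	N		HexNAc4Hex3
G0F	N-glycan	N		HexNAc4Hex3Fuc1
G1F	N-glycan	N		HexNAc4Hex4Fuc1
G2F	N-glycan	N		HexNAc4Hex5Fuc1
Man5	N-glycan	N		HexNAc2Hex5
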