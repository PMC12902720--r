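# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
# columns: symbol	monoisotopic_mass
symbol	monoisotopic_mass
H	1.0078250319
C	12.0000000000
N	14.0030740052
O	15.9949146221
S	31.9720706900
P	30.9737615100
2H	2.0141017780
13C	13.0033548378
15N	15.0001088984
18O	17.9991604000
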