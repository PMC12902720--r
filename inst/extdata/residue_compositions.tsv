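# Amino-acid residue (dehydrated) elemental compositions.
# columns: code	name	formula (Hill-style element+count tokens)
code	name	formula
G	Glycine	C2H3NO
A	Alanine	C3H5NO
S	Serine	C3H5NO2
P	Proline	C5H7NO
V	Valine	C5H9NO
T	Threonine	C4H7NO2
C	Cysteine	C3H5NOS
L	Leucine	C6H11NO
I	Isoleucine	C6H11NO
N	Asparagine	C4H6N2O2
D	Aspartate	C4H5NO3
Q	Glutamine	C5H8N2O2
K	Lysine	C6H12N2O
E	Glutamate	C5H7NO3
M	Methionine	C5H9NOS
H	Histidine	C6H7N3O
F	Phenylalanine	C9H9NO
R	Arginine	C6H12N4O
Y	Tyrosine	C9H9NO2
W	Tryptophan	C11H10N2O
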