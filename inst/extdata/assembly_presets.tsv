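id	species	scaffold_n50	category
A	Drosophila melanogaster (divided chromosomes)	NA	Excellent
B	Aedes aegypti	409777670	Excellent
C	Ctenocephalides felis	71713785	Very Good
D	Apis mellifera	13619445	Very Good
E	Papilio xuthus	6198915	Good
F	Schizaphis graminum	1292312	Good
G	Pogonomyrmex barbatus	819605	Medium
H	Bactrocera oleae	139566	Medium
I	Lutzomyia longipalpis	85093	Poor
J	Drosophila albomicans	23589	Poor
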