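# Canonical PlantCARE-style cis-regulatory element consensi with functional
# classes (hormone / stress / growth / core / other). Editable; this shipped
# set is a documented approximation of the full PlantCARE catalog.
name	consensus	class
TATA-box	TATAAA	core
CAAT-box	CCAAT	core
ABRE	ACGTG	hormone
SARE	TTCGACCATCTT	hormone
TCA-element	CCATCTTTTT	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
GARE-motif	TCTGTTG	hormone
P-box	CCTTTTG	hormone
TGA-element	AACGAC	hormone
AuxRR-core	GGTCCAT	hormone
ARE	AAACCA	stress
MBS	CAACTG	stress
LTR	CCGAAA	stress
TC-rich_repeats	ATTCTCTAAC	stress
W-box	TTGACC	stress
G-box	CACGTG	stress
Box-4	ATTAAT	stress
GT1-motif	GGTTAA	stress
Skn-1_motif	GTCAT	growth
GCN4_motif	TGAGTCA	growth
RY-element	CATGCATG	growth
CAT-box	GCCACT	growth
O2-site	GATGACATGG	growth
circadian	CAAAGATATC	other
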