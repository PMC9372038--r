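name	pattern	category
ABRE	ACGTG	phytohormone_responsiveness
TCA-element	CCATCTTTTT	phytohormone_responsiveness
ERE	ATTTCAAA	phytohormone_responsiveness
TGACG-motif	TGACG	phytohormone_responsiveness
CGTCA-motif	CGTCA	phytohormone_responsiveness
MYC	CATTTG	phytohormone_responsiveness
TGA-element	AACGAC	phytohormone_responsiveness
MBS	CAACTG	stress_responsiveness
ARE	AAACCA	stress_responsiveness
TC-rich repeats	GTTTTCTTAC	stress_responsiveness
As-1 element	TGACGTCA	stress_responsiveness
STRE	AGGGG	stress_responsiveness
LTR	CCGAAA	stress_responsiveness
WRE3	CCACCT	stress_responsiveness
WUN-motif	AAATTTCCT	stress_responsiveness
CAT-box	GCCACT	growth_development
GCN4-motif	TGAGTCA	growth_development
AAGAA-motif	GAAAGAA	growth_development
CCAAT-box	CAACGG	growth_development
AT-rich element	ATAGAAATCAA	growth_development
Circadian	CAANNNNATC	growth_development
O2-site	GATGACATGG	growth_development
TATA-box	TATAAA	core_promoter
CAAT-box	CCAAT	core_promoter
Unnamed_1	CGTGGA	uncharacterized
Unnamed_2	GTCTCTCC	uncharacterized
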