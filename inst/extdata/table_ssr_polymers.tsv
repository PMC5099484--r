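ssr_type	motif	copies	size_bp	location
penta	TATTA	3	15	IGS (rps10-exon1, atp1)
penta	AAAAT	3	15	IGS (nad9, nad4-exon4)
penta	GTCTG	3	15	nad4-intron3
penta	GTTTT	4	20	IGS (trnS-UGA, nad1-exon4)
penta	ACTAG	3	15	matR
penta	CTTAG	3	15	IGS (rps14, rps4)
penta	ATTAC	3	15	IGS (trnS-GCU, nad4L)
penta	CCTTT	3	15	IGS (atp8, nad1-exon1)
penta	AAAAT	3	15	IGS (nad9, nad4-exon4)
penta	GTCTG	3	15	nad4-intron3
penta	AATAA	3	15	IGS (trnG-GCC, trnQ-UUG)
penta	TTTTA	5	25	IGS (atp4, ccmFc-exon1)
hexa	ACCAAT	3	18	IGS (rps4, cox2-exon1)
hexa	TTCTCT	3	18	IGS (trnQ-UUG, nad6)
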