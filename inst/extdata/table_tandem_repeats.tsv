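number	size_bp	unit	copies	location
1	15	TAAGTGAAATAAAAT	2	IGS (nad4-exon1, trnD-GUC)
2	21	TAACAGAAGTTTCAAGAGAAC	2	IGS (nad7-exon5, ccmB)
3	36	TCGGAAAAACAAATGCCATGAAGGACTTAGGAAAGA	2	IGS (nad2-exon5, rpl2)
4	26	GATCGCCGTCAAAGACAGGATTCGAG	2	IGS (rps14, rps4)
5	15	TAAGTGAAATAAAAT	2	IGS (nad4-exon1, trnD-GUC)
6	42	CTTGGCTTTCCTTTTTGTCTTGACTCTATGCCTTCCAGCTGT	2	IGS (sdh3, atp4)
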