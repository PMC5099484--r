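cluster	gene1	gene1_start	gene1_end	gene2	gene2_start	gene2_end	printed_interval
sdh4-cox3	sdh4	32397	32795	cox3	32723	33520	-72
cox1-rps10	cox1	34397	36529	rps10	36716	37897	186
rrn5-rrn18	rrn5	53358	53467	rrn18	53640	55596	163
mttB-nad9	mttB	82795	83595	nad9	83780	84352	184
nad3-rps12	nad3	114810	115166	rps12	115215	115586	48
nad1d-matR	nad1d	164104	164162	matR	164824	166791	661
matR-nad1e	matR	164824	166791	nad1e	167598	167856	806
rpl2-rpl5	rpl2	258634	259638	rpl5	260136	260717	497
rpl5-nad5c	rpl5	260136	260717	nad5c	261835	261856	1117
cob-rps14	cob	273866	275044	rps14	276398	276700	1353
rpl16-rps3	rpl16	318985	319419	rps3	319391	322790	-28
nad5ab-atp9	nad5ab	475056	477354	atp9	477575	477886	220
nad2abc-sdh3	nad2abc	643910	645676	sdh3	646583	647017	906
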