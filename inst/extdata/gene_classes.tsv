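prefix	class
nad	Complex I (NADH dehydrogenase)
sdh	Complex II (succinate dehydrogenase)
cob	Complex III (ubiquinol cytochrome c reductase)
cox	Complex IV (cytochrome c oxidase)
atp	Complex V (ATP synthase)
ccm	Cytochrome c biogenesis
rps	Ribosomal proteins (SSU)
rpl	Ribosomal proteins (LSU)
matr	Maturases
mttb	Transport membrane protein
rrn	Ribosomal RNAs
trn	Transfer RNAs
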