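ligand	receptor
Ccl2	Ccr2
Ccl7	Ccr2
Ccl24	Ccr2
Cxcl12	Cxcr4
Il1b	Il1r2
Il1b	Il1r1
Il6	Il6ra
Tnf	Tnfrsf1a
Col1a1	Cd44
Col1a2	Itgav
Col3a1	Ddr1
Timp1	Cd36
C1qa	Lrp1
Csf1	Csf1r
Pdgfa	Pdgfra
Pdgfb	Pdgfrb
Vegfa	Flt1
Fn1	Itgb1
Spp1	Cd44
Apoe	Lrp1
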