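##gff-version 3
# synthetic psbF-psbL operon analog; coordinates 1-based
# C-to-U editing site at position 107 (+ strand); poly-T SSR run 98-106
psbF_operon_synthetic	chloroslip	CDS	31	150	.	+	0	ID=psbF;Name=psbF
psbF_operon_synthetic	chloroslip	CDS	230	289	.	+	0	ID=psbL;Name=psbL
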