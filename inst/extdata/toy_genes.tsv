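gene	chrom	strand	tss	body_start	body_end
gA	chr1	+	10000	10000	12000
gB	chr1	-	30000	28000	30000
gC	chr2	+	5000	5000	8000
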