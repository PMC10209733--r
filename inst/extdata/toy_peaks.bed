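chr1	9900	10400	pkA
chr1	20000	20500	pkB
chr2	4900	5400	pkC
chr2	50000	50500	pkD
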