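variant	population	allele_count	allele_number
c.1400C>G	CNGP	150	35728
c.1400C>G	gnomAD_NFE	0	35000
c.760C>T	CNGP	27	35728
c.760C>T	gnomAD_NFE	0	35000
c.136C>T	CNGP	1	35728
c.136C>T	gnomAD_NFE	32	35000
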