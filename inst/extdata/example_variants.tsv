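hgvs_c	hgvs_p	location_kind	exon_number	domain	mutation_type	acmg_class
c.1400C>G	p.S467C	exon	8	non_transmembrane	missense	P
c.760C>T	p.R254*	exon	4	non_transmembrane	nonsense	P
c.51C>G	p.F17L	exon	1	transmembrane	missense	LP
c.497+1G>T		intron		unassigned	splicing	P
c.844C>T	p.R282*	exon	5	non_transmembrane	nonsense	P
c.136C>T	p.P46S	exon	1	transmembrane	missense	VUS
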