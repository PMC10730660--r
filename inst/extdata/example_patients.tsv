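id	age_group	allele1_hgvs	allele1_type	allele2_hgvs	allele2_type	phenotypes
PT01	infant_child	c.760C>T	nonsense	c.760C>T	nonsense	cardiomyopathy;hypoglycemia
PT02	infant_child	c.1400C>G	missense	c.1400C>G	missense	asymptomatic
PT03	infant_child	c.760C>T	nonsense	c.1400C>G	missense	hepatomegaly
PT04	adult	c.1400C>G	missense	c.51C>G	missense	fatigue
PT05	infant_child	c.844C>T	nonsense	c.844C>T	nonsense	cardiomyopathy;cardiac_failure
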