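code	parent_base	formula	base_formula	description
A	A	C10H12N5O6P	C5H5N5	adenosine
C	C	C9H12N3O7P	C4H5N3O	cytidine
G	G	C10H12N5O7P	C5H5N5O	guanosine
U	U	C9H11N2O8P	C4H4N2O2	uridine
m5C	C	C10H14N3O7P	C5H7N3O	5-methylcytidine
m7G	G	C11H14N5O7P	C6H7N5O	7-methylguanosine
m1A	A	C11H14N5O6P	C6H7N5	1-methyladenosine
m22G	G	C12H16N5O7P	C7H9N5O	N2,N2-dimethylguanosine
D	U	C9H13N2O8P	C4H6N2O2	dihydrouridine
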