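res_pos	name_pos	res_neg	name_neg	interface
106	ARG	177	GLU	a-b
106	ARG	180	ASP	a-b
114	LYS	180	ASP	a-b
114	LYS	181	ASP	a-b
120	ARG	181	ASP	a-b
132	ARG	180	ASP	a-b
132	ARG	181	ASP	a-b
97	ARG	242	GLU	a-b'
97	ARG	297	ASP	a-b'
97	ARG	321	GLU	a-b'
97	ARG	322	GLU	a-b'
97	ARG	323	GLU	a-b'
326	LYS	431	GLU	b'-a'
308	LYS	359	GLU	b'-x
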