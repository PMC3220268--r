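res_name	atom_name	role
ARG	NE	donor
ARG	NH1	donor
ARG	NH2	donor
LYS	NZ	donor
TYR	OH	donor
GLU	OE1	acceptor
GLU	OE2	acceptor
ASP	OD1	acceptor
ASP	OD2	acceptor
TPO	O1P	acceptor
TPO	O2P	acceptor
TPO	O3P	acceptor
TPO	OG1	acceptor
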