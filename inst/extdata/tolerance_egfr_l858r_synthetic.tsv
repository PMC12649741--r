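pam_index	new_base	indel_rate	source
1	A	0.18	synthetic-example
1	G	0.05	synthetic-example
1	T	0.11	synthetic-example
3	A	0.22	synthetic-example
3	C	0.09	synthetic-example
3	G	0.31	synthetic-example
6	C	0.12	synthetic-example
6	G	0.27	synthetic-example
6	T	0.06	synthetic-example
9	A	0.44	synthetic-example
9	G	0.19	synthetic-example
9	T	0.25	synthetic-example
11	A	0.33	synthetic-example
11	C	0.15	synthetic-example
11	T	0.38	synthetic-example
15	A	0.41	synthetic-example
15	C	0.28	synthetic-example
15	T	0.35	synthetic-example
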