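pam_index	new_base	indel_rate	source
3	A	0.52	synthetic-example
3	C	0.34	synthetic-example
3	G	0.61	synthetic-example
6	C	0.29	synthetic-example
6	G	0.55	synthetic-example
6	T	0.18	synthetic-example
9	A	0.47	synthetic-example
9	C	0.58	synthetic-example
9	G	0.39	synthetic-example
12	C	0.51	synthetic-example
12	G	0.62	synthetic-example
12	T	0.44	synthetic-example
15	A	0.57	synthetic-example
15	C	0.49	synthetic-example
15	T	0.66	synthetic-example
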