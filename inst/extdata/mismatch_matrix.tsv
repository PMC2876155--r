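original	replacement	successes	trials
A	A	0	10
A	T	5	10
A	G	6	10
A	C	6	10
T	A	6	10
T	T	0	10
T	G	9	10
T	C	1	10
G	A	5	10
G	T	9	10
G	G	0	10
G	C	4	10
C	A	6	10
C	T	4	10
C	G	4	10
C	C	0	10
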