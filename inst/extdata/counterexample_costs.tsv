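	a	c	g	n	t	v
a	0	10	10	10	10	10
c	10	0	10	10	10	10
g	10	10	0	10	10	10
n	10	10	10	0	10	10
t	10	10	10	10	0	10
v	10	10	10	10	10	0
indel	1
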