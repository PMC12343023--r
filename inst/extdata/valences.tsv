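# Allowed valences per element and formal charge (neutral organic rules;
# charged states follow the usual electron-count adjustment).
element	charge	valence
H	0	1
H	1	0
H	-1	0
C	0	4
C	1	3
C	-1	3
N	0	3
N	1	4
N	-1	2
O	0	2
O	1	3
O	-1	1
F	0	1
F	-1	0
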