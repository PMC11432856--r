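clade	Atlantic	Mediterranean
1	5	7
2	3	1
3	25	32
4A	2	0
4B	2	4
4C	0	49
4D	0	9
4E	107	18
4F	17	3
4G	4	3
4H	0	5
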