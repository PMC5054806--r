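1	pp	2
2	pp	3
3	pp	4
1	pp	4
1	pp	7
4	pp	5
2	pp	8
3	pp	10
6	pp	7
7	pp	8
5	pp	6
5	pp	10
8	pp	9
9	pp	10
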