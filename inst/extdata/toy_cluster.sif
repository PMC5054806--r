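1	pp	8
8	pp	7
7	pp	4
4	pp	9
8	pp	10
10	pp	4
1	pp	2
2	pp	3
3	pp	5
5	pp	6
6	pp	7
5	pp	7
3	pp	6
2	pp	8
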