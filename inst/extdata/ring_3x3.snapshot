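goodwave_snapshot: 1
height: 3
width: 3
t: 0

---
row	col	p	strain
1	1	6	0
2	1	6	0
3	1	6	0
1	2	6	0
3	2	6	0
1	3	6	0
2	3	6	0
3	3	6	0
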