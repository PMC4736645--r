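goodwave_snapshot: 1
height: 5
width: 5
t: 0

---
row	col	p	strain
3	3	6	0
3	4	6	0
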