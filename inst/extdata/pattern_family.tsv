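gene_id	c1	c2	c3	c4	c5	c6	c7	c8	c9
a	4	7	6	3	6	5	8	7	3
b1	10	13	12	9	12	11	14	13	9
b2	10.4286	12.5714	11.8571	9.7143	11.8571	11.1429	13.2857	12.5714	9.7143
b3	10.8571	12.1429	11.7143	10.4286	11.7143	11.2857	12.5714	12.1429	10.4286
b4	11.2857	11.7143	11.5714	11.1429	11.5714	11.4286	11.8571	11.7143	11.1429
b5	11.7143	11.2857	11.4286	11.8571	11.4286	11.5714	11.1429	11.2857	11.8571
b6	12.1429	10.8571	11.2857	12.5714	11.2857	11.7143	10.4286	10.8571	12.5714
b7	12.5714	10.4286	11.1429	13.2857	11.1429	11.8571	9.7143	10.4286	13.2857
b8	13	10	11	14	11	12	9	10	14
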