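chrom	start_kb	end_kb	method
3	47927	48527	hapFLK
7	74411	75011	hapFLK
13	77582	78182	hapFLK
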