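chrom	start_kb	end_kb	method
2	58551	59151	FST
2	119989	120589	FST
3	3456	4056	FST
3	47927	48527	FST
3	166043	166643	FST
4	22288	22888	FST
4	78819	79419	FST
7	59416	60016	FST
8	60397	60997	FST
9	20526	21126	FST
13	22489	23089	FST
14	47470	48070	FST
16	31025	31625	FST
18	57744	58344	FST
19	14930	15530	FST
20	44180	44780	FST
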