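event_id	chrom	start	end	kind	P01	P08	P15	P20	P28	P36	P45
2:30000001-45000000:cnloh	2	30000001	45000000	cnloh	1	1	1	1	1	1	1
3:150000001-160000000:loss	3	150000001	160000000	loss	0.95	0.85	0.6	0.4	0.25	0.1	0.05
7:65000001-90000000:gain	7	65000001	90000000	gain	0.95	0.85	0.6	0.4	0.25	0.1	0.05
1:120000001-150000000:loss	1	120000001	150000000	loss	0	0.05	0.3	0.55	0.7	0.85	0.9
5:40000001-70000000:gain	5	40000001	70000000	gain	0	0.05	0.3	0.55	0.7	0.85	0.9
9:1-25000000:cnloh	9	1	25000000	cnloh	0	0.05	0.3	0.55	0.7	0.85	0.9
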