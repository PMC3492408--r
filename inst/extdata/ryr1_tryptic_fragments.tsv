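fragment_id	apparent_kda	nterm_read	labeled	parent_id	known_start	known_end
1	170	TQVKGVGQN	TRUE	NA	3120	4673
2	NA	NA	FALSE	1	3120	4475
3	145	ND	TRUE	NA	1	1302
6	110	AVVAXFRMTP	TRUE	1	3631	4673
7	102	ISHTDLVIG	TRUE	NA	1509	2399
8	95	GSGPPAGPAL	TRUE	3	427	1302
9	NA	NA	FALSE	6	3631	4475
11	70	KLGVDGEEEE	TRUE	NA	4476	5037
12	NA	NA	FALSE	7	NA	NA
14	NA	NA	FALSE	7	NA	NA
15	45	RREHFGEEPP	TRUE	NA	2402	2795
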