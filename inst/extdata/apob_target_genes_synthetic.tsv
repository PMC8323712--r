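gene	chrom	start	end
ABCG5_8	1	1000000	1050000
ANGPTL3	2	1000000	1050000
ANGPTL4	3	1000000	1050000
ANGPTL8	4	1000000	1050000
APOC3_APOA5	5	1000000	1050000
APOB	6	1000000	1050000
CETP	7	1000000	1050000
DGAT	8	1000000	1050000
HMGCR	9	1000000	1050000
LDLR	10	1000000	1050000
LPL	11	1000000	1050000
MTTP	12	1000000	1050000
NPC1L1	13	1000000	1050000
PCSK9	14	1000000	1050000
PPARA	15	1000000	1050000
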