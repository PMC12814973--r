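snp_a	snp_b	plink_lr	plink_boost	mbmdr_adj	mbmdr_noadj	epiblaster	lightgbm	effect
rs10489136	rs6702469	NA	NA	NA	NA	NA	NA	joint_recessive
rs10492963	rs11801629	2	2	1	NA	2	14	joint_dominant
rs16837624	rs6693450	1	1	2	NA	1	10	exponential
rs17130482	rs1876839	NA	NA	NA	3	NA	15	triplet
rs17130482	rs6702469	NA	NA	NA	NA	NA	7	triplet
rs1876839	rs6702469	NA	NA	NA	2	NA	12	triplet
rs4653522	rs6576939	NA	NA	NA	NA	NA	11	multiplicative
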