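#taxon	AEK
#species	Ancestral Eutherian karyotype (2n=48)
#diploid_number_reported	48
#sex_chromosome_count	2
#note	Hypothetical ancestral Eutherian karyotype, 2n=48: HSA 1, 2p, 2q, 3/21, 4/8p, 5, 6, 7a, 7b/16p, 8q, 9, 10p, 10q, 11, 12/22 twice, 13, 14/15, 16q/19q, 17, 18, 19p, 20 and X. Used as the outgroup pseudo-taxon.
chrom_id	segments	flags
AEK_01	1	
AEK_02	2p	
AEK_03	2q	
AEK_04	3,21	
AEK_05	4,8p	
AEK_06	5	
AEK_07	6	
AEK_08	7a	
AEK_09	7b,16p	
AEK_10	8q	
AEK_11	9	
AEK_12	10p	
AEK_13	10q	
AEK_14	11	
AEK_15	12a,22a	
AEK_16	12b,22b	
AEK_17	13	
AEK_18	14,15	
AEK_19	16q,19q	
AEK_20	17	
AEK_21	18	
AEK_22	19p	
AEK_23	20	
AEK_X	X	sex
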