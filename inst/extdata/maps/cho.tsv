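#taxon	CHO
#species	Choloepus hoffmanni
#diploid_number_reported	50
#sex_chromosome_count	2
#probes_failed	Y
#note	Human-probe painting of C. hoffmanni (2n=50), from published work. A small distal segment of the chromosome painted by HSA 7 (CHO_13) was labeled by no probe and may correspond to HSA 10. The third HSA 8 block is uncertain ("8?").
chrom_id	segments	flags
CHO_01	3,21	
CHO_02	4,8a	
CHO_03	7a,16a	
CHO_04	12a,22a	
CHO_05	12b,22b	
CHO_06	14,15	
CHO_07	16b,19a	
CHO_08	1	
CHO_09	2a	
CHO_10	2b	
CHO_11	5	
CHO_12	6	
CHO_13	7b	unpainted_regions:1
CHO_14	8b	
CHO_15	8c	uncertain
CHO_16	9	
CHO_17	10	
CHO_18	11	
CHO_19	13	
CHO_20	16c	
CHO_21	17	
CHO_22	18	
CHO_23	19b	
CHO_24	20	
CHO_X	X	sex
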