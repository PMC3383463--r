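#taxon	BTR
#species	Bradypus tridactylus
#diploid_number_reported	52
#sex_chromosome_count	2
#probes_failed	Y
#note	INFERRED map (2n=52): human-probe homology deduced by chaining C. didactylus paints on B. tridactylus with human paints on C. didactylus. The third HSA 8 block is uncertain (the CDI 18 = HSA 2/8 probe did not hybridize). The transcribed inventory reaches 24 pairs of the reported 26; the balance is unresolved in the source data.
chrom_id	segments	flags
BTR_01	2a,6a	
BTR_02	3a,21	
BTR_03	4a,8a	
BTR_04	7a,10a	
BTR_05	7b,16a	
BTR_06	11,19a	
BTR_07	12a,22a	
BTR_08	12b,22b,16b	unordered
BTR_09	14,15	
BTR_10	17,19b	
BTR_11	1	
BTR_12	2b	
BTR_13	3b	
BTR_14	4b	
BTR_15	5	
BTR_16	6b	
BTR_17	6c	
BTR_18	8b	
BTR_19	9	
BTR_20	10b	
BTR_21	13	
BTR_22	18	
BTR_23	20	
BTR_24	8c	uncertain
BTR_X	X	sex
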