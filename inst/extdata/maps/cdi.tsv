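#taxon	CDI
#species	Choloepus didactylus
#diploid_number_reported	65
#sex_chromosome_count	1
#probes_failed	Y
#note	Human-probe painting of C. didactylus (2n=65), from published work. The odd diploid number reflects a Y/autosome translocation: the X is unpaired in males, so the complement is 32 autosome pairs + X.
chrom_id	segments	flags
CDI_01	2a,8a	
CDI_02	3a,21	
CDI_03	4a,8b	
CDI_04	7a,10a	
CDI_05	7b,16a	
CDI_06	12a,22a	
CDI_07	12b,22b	
CDI_08	14a,15	
CDI_09	1a	
CDI_10	1b	
CDI_11	2b	
CDI_12	2c	
CDI_13	3b	
CDI_14	4b	
CDI_15	5a	
CDI_16	5b	
CDI_17	6a	
CDI_18	6b	
CDI_19	7c	
CDI_20	8c	
CDI_21	9	
CDI_22	10b	
CDI_23	11a	
CDI_24	11b	
CDI_25	13	
CDI_26	14b	
CDI_27	16b	
CDI_28	17	
CDI_29	18	
CDI_30	19a	
CDI_31	19b	
CDI_32	20	
CDI_X	X	sex
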