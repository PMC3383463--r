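#taxon	AEKALT
#species	Ancestral Eutherian karyotype, alternative (2n=46)
#diploid_number_reported	46
#sex_chromosome_count	2
#note	Alternative ancestral Eutherian karyotype, 2n=46, differing from the 2n=48 version only by the additional association HSA 10p/12/22.
chrom_id	segments	flags
AEKALT_01	1	
AEKALT_02	2p	
AEKALT_03	2q	
AEKALT_04	3,21	
AEKALT_05	4,8p	
AEKALT_06	5	
AEKALT_07	6	
AEKALT_08	7a	
AEKALT_09	7b,16p	
AEKALT_10	8q	
AEKALT_11	9	
AEKALT_12	10p,12a,22a	
AEKALT_13	10q	
AEKALT_14	11	
AEKALT_15	12b,22b	
AEKALT_16	13	
AEKALT_17	14,15	
AEKALT_18	16q,19q	
AEKALT_19	17	
AEKALT_20	18	
AEKALT_21	19p	
AEKALT_22	20	
AEKALT_X	X	sex
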