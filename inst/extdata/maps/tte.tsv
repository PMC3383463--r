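#taxon	TTE
#species	Tamandua tetradactyla
#diploid_number_reported	54
#sex_chromosome_count	2
#probes_failed	Y
#note	Human-probe painting of T. tetradactyla (2n=54), from published work; the most rearranged xenarthran karyotype painted to date. The printed association list is realized literally (7/20 and 20/7/10 as separate chromosomes), which makes the structural block counts for HSA 7, 20 and 22 exceed the printed table cells by one each; those three cells are flagged for the inference layer.
chrom_id	segments	flags
TTE_01	1a,9	
TTE_02	1b,13	
TTE_03	1c,19a	
TTE_04	2a,8a	
TTE_05	3a,6a	
TTE_06	3b,21	
TTE_07	3c,22a	
TTE_08	4a,8b	
TTE_09	5a,11a	
TTE_10	7a,16a	
TTE_11	8c,17	
TTE_12	12a,22b	
TTE_13	12b,22c	
TTE_14	14a,15a	
TTE_15	14b,15b	
TTE_16	16b,19b	
TTE_17	7b,20a	
TTE_18	20b,7c,10	
TTE_19	2b	
TTE_20	4b	
TTE_21	4c	
TTE_22	5b	
TTE_23	5c	
TTE_24	6b	
TTE_25	11b	
TTE_26	18	
TTE_X	X	sex
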