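#taxon	DNO
#species	Dasypus novemcinctus
#diploid_number_reported	64
#sex_chromosome_count	2
#probes_failed	Y
#note	Human-probe painting of D. novemcinctus (2n=64), from published work. A third HSA 2 block ("2?") and a second free HSA 19 block ("19?") are uncertain. The chromosome painted by HSA 7 carries an unlabeled distal segment that may correspond to HSA 10.
chrom_id	segments	flags
DNO_01	3a,21a	
DNO_02	3b,21b	
DNO_03	4a,8a	
DNO_04	7a,16a	
DNO_05	10a,12a	
DNO_06	12b,22a	
DNO_07	12c,22b	
DNO_08	14,15	
DNO_09	16b,19a	
DNO_10	1a	
DNO_11	1b	
DNO_12	2a	
DNO_13	2b	
DNO_14	2c	uncertain
DNO_15	3c	
DNO_16	4b	
DNO_17	5	
DNO_18	6a	
DNO_19	6b	
DNO_20	7b	unpainted_regions:1
DNO_21	8b	
DNO_22	8c	
DNO_23	9	
DNO_24	10b	
DNO_25	11a	
DNO_26	11b	
DNO_27	13	
DNO_28	17	
DNO_29	18	
DNO_30	19b	uncertain
DNO_31	20	
DNO_X	X	sex
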