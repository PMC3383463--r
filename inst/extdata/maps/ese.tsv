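#taxon	ESE
#species	Euphractus sexcinctus
#diploid_number_reported	58
#sex_chromosome_count	2
#probes_failed	Y
#note	Human-probe painting of E. sexcinctus (2n=58), from published work. The transcribed segment inventory tiles 30 autosome pairs against 28 reported; the published summary omits structural detail, so the reported 2n is kept as metadata and the mismatch flagged as an advisory.
chrom_id	segments	flags
ESE_01	2a,8a	
ESE_02	3a,21	
ESE_03	4a,8b	
ESE_04	7a,10a	
ESE_05	7b,16a	
ESE_06	12a,22a	
ESE_07	12b,22b	
ESE_08	14,15	
ESE_09	16b,19a	
ESE_10	1a	
ESE_11	1b	
ESE_12	2b	
ESE_13	2c	
ESE_14	3b	
ESE_15	3c	
ESE_16	4b	
ESE_17	4c	
ESE_18	5	
ESE_19	6a	
ESE_20	6b	
ESE_21	8c	
ESE_22	9	
ESE_23	10b	
ESE_24	11a	
ESE_25	11b,19b	
ESE_26	12c	
ESE_27	13	
ESE_28	17	
ESE_29	18	
ESE_31	20	
ESE_X	X	sex
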