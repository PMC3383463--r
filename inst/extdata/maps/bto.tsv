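#taxon	BTO
#species	Bradypus torquatus
#diploid_number_reported	50
#sex_chromosome_count	2
#probes_failed	Y
#note	Human-probe painting of a male B. torquatus (2n=50). Chromosome ids are arbitrary except BTO_23 (euchromatic pair painted by no probe). Pericentromeric and other C-band-positive regions are unlabeled and excluded from counts.
chrom_id	segments	flags
BTO_01	3,21	
BTO_02	4,8a	
BTO_03	7a,10a	
BTO_04	7b,16a	
BTO_05	12a,22a	
BTO_06	12b,22b	
BTO_07	14,15	
BTO_08	17,19a	
BTO_09	1	het_regions:2
BTO_10	2a	
BTO_11	2b	
BTO_12	5	
BTO_13	6	
BTO_14	8b	
BTO_15	8c	
BTO_16	9	
BTO_17	10b	
BTO_18	11	
BTO_19	13	
BTO_20	16b	
BTO_21	18	
BTO_22	20	
BTO_24	19b	
BTO_23		unpainted
BTO_X	X	sex
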