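#taxon	BVA
#species	Bradypus variegatus
#diploid_number_reported	54
#sex_chromosome_count	2
#probes_failed	21,Y
#note	Human-probe painting of B. variegatus (2n=54). The HSA 21 probe gave no hybridization; the distal euchromatic segment of BVA_01 (proximally painted by HSA 3) very likely corresponds to HSA 21, stored as an uncertain segment. BVA_25 is a euchromatic pair painted by no probe.
chrom_id	segments	flags
BVA_01	3a,21?	unpainted_regions:1
BVA_02	4a,8a	
BVA_03	7a,10a	
BVA_04	7b,16a	
BVA_05	12a,22a	
BVA_06	16b,12b,22b,16c	unordered
BVA_07	14,15	
BVA_08	17,19a	
BVA_09	1a	
BVA_10	1b	
BVA_11	2a	
BVA_12	2b	
BVA_13	3b	
BVA_14	4b	
BVA_15	5	
BVA_16	6	
BVA_17	8b	
BVA_18	8c	
BVA_19	9	
BVA_20	10b	
BVA_21	11	
BVA_22	13	
BVA_23	18	het_regions:2
BVA_24	19b	
BVA_25		unpainted
BVA_26	20	
BVA_X	X	sex
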