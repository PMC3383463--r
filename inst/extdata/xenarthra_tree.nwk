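(AEK,((DNO,ESE)Cingulata,(TTE,((BTO,(BVA,BTR)BradypusCrown)Bradypus,(CHO,CDI)Choloepus)Folivora)Pilosa)Xenarthra)Eutheria;
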