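strain_id	origin_group	papC	papGIII	sfa_foc	iha	hra	ibeA	fyuA	irp2	iroN	aer	ireA	kpsMTII	neuC	ompT	traT	hlyC	cnf1	usp	sat	clbQ
human_exclusive_r01	human_exclusive	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
human_exclusive_r02	human_exclusive	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
human_exclusive_r03	human_exclusive	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
human_exclusive_r04	human_exclusive	1	0	1	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
human_exclusive_r05	human_exclusive	1	0	1	0	1	1	1	1	1	1	0	1	1	1	1	1	1	1	0	1
human_exclusive_r06	human_exclusive	1	0	1	0	1	1	1	1	1	1	0	1	1	1	1	1	1	1	0	1
human_exclusive_r07	human_exclusive	1	0	1	0	1	1	1	1	1	1	0	1	1	1	1	1	0	1	0	1
human_exclusive_r08	human_exclusive	1	0	1	0	0	1	1	1	1	1	0	1	1	1	1	0	0	1	0	1
human_exclusive_r09	human_exclusive	1	0	1	0	0	0	1	1	1	0	0	1	1	1	1	0	0	1	0	1
human_exclusive_r10	human_exclusive	0	0	1	0	0	0	1	1	1	0	0	1	1	1	1	0	0	1	0	1
human_exclusive_r11	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	1	1	1	0	0	0	1	0	1
human_exclusive_r12	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	1	1	1	0	0	0	1	0	1
human_exclusive_r13	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	0	0	1	0	0	0	1	0	0
human_exclusive_r14	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	0	0	1	0	0	0	1	0	0
human_exclusive_r15	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	0	0	1	0	0	0	1	0	0
human_exclusive_r16	human_exclusive	0	0	0	0	0	0	1	1	1	0	0	0	0	1	0	0	0	1	0	0
human_exclusive_r17	human_exclusive	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	1	0	0
human_exclusive_r18	human_exclusive	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	1	0	0
human_exclusive_r19	human_exclusive	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	1	0	0
human_exclusive_r20	human_exclusive	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
human_nonexclusive_r01	human_nonexclusive	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
human_nonexclusive_r02	human_nonexclusive	1	0	0	1	0	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1
human_nonexclusive_r03	human_nonexclusive	1	0	0	1	0	1	1	1	1	0	1	1	1	1	1	0	0	1	1	0
human_nonexclusive_r04	human_nonexclusive	1	0	0	1	0	1	1	1	1	0	1	1	1	1	1	0	0	1	0	0
human_nonexclusive_r05	human_nonexclusive	0	0	0	0	0	0	1	1	1	0	0	1	1	1	1	0	0	1	0	0
human_nonexclusive_r06	human_nonexclusive	0	0	0	0	0	0	1	1	1	0	0	1	0	1	1	0	0	1	0	0
human_nonexclusive_r07	human_nonexclusive	0	0	0	0	0	0	1	1	0	0	0	1	0	1	1	0	0	1	0	0
human_nonexclusive_r08	human_nonexclusive	0	0	0	0	0	0	1	1	0	0	0	0	0	1	1	0	0	1	0	0
human_nonexclusive_r09	human_nonexclusive	0	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	1	0	0
human_nonexclusive_r10	human_nonexclusive	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
animal_r01	animal	0	0	1	0	1	1	1	1	1	1	1	1	1	1	1	1	0	1	0	1
animal_r02	animal	0	0	1	0	1	1	1	1	1	0	1	1	1	1	1	0	0	1	0	1
animal_r03	animal	0	0	0	0	1	1	1	1	1	0	1	1	1	1	1	0	0	1	0	0
animal_r04	animal	0	0	0	0	1	1	1	1	1	0	1	1	0	1	1	0	0	1	0	0
animal_r05	animal	0	0	0	0	1	1	1	1	1	0	0	1	0	1	1	0	0	1	0	0
animal_r06	animal	0	0	0	0	0	1	1	1	1	0	0	1	0	1	1	0	0	1	0	0
animal_r07	animal	0	0	0	0	0	0	1	1	0	0	0	1	0	1	0	0	0	0	0	0
animal_r08	animal	0	0	0	0	0	0	1	1	0	0	0	1	0	1	0	0	0	0	0	0
animal_r09	animal	0	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	0	0	0
animal_r10	animal	0	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	0	0	0
animal_r11	animal	0	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	0	0	0
animal_r12	animal	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
animal_r13	animal	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
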