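sample_id	total_cfu	b1_cfu	b2_cfu	d_cfu	yjaa_cfu
E1_0001	47523900	2782480	28568100	3434650	35888200
E1_0002	151971	7273.66	116118	14853.6	120485
E1_0003	4049140	309966	3222190	268665	4008790
E2_0001	2207990	1221300	66448	519696	255581
E2_0002	1183530	657388	50192.3	267129	146582
E2_0003	9178860	4770350	419203	2248430	1114970
E3_0001	5090610	1224550	82740.9	716914	1554650
E3_0002	23712800	4969880	1954190	5499610	8588010
E3_0003	5209690	1269400	329436	709017	1769260
E4_0001	600255000	8105010	659857000	7047970	694709000
E4_0002	9172250	85248.9	7082830	81028.5	7695390
E4_0003	28754100	316723	27525200	548041	27428500
E5_0001	37021200	6179130	3630740	4568590	14863300
E5_0002	66939100	15054900	7836260	10196300	25526800
E5_0003	109776000	13766300	7527360	17923500	39300300
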