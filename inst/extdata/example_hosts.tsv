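sample_id	species	habitat	diet
E1_0001	deer	wild	herbivorous
E1_0002	wild_rabbit	wild	herbivorous
E1_0003	wild_rabbit	wild	herbivorous
E2_0001	domesticated_rabbit	domesticated	herbivorous
E2_0002	sheep	domesticated	herbivorous
E2_0003	horse	domesticated	herbivorous
E3_0001	chicken	domesticated	omnivorous
E3_0002	pig	domesticated	omnivorous
E3_0003	pig	domesticated	omnivorous
E4_0001	human	human	omnivorous
E4_0002	human	human	omnivorous
E4_0003	human	human	omnivorous
E5_0001	human	human	omnivorous
E5_0002	human	human	omnivorous
E5_0003	human	human	omnivorous
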