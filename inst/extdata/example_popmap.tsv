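pair1_pop1_1	island_a
pair1_pop1_2	island_a
pair1_pop1_3	island_a
pair1_pop1_4	island_a
pair1_pop1_5	island_a
pair1_pop1_6	island_a
pair1_pop1_7	island_a
pair1_pop1_8	island_a
pair1_pop1_9	island_a
pair1_pop1_10	island_a
pair1_pop2_1	island_b
pair1_pop2_2	island_b
pair1_pop2_3	island_b
pair1_pop2_4	island_b
pair1_pop2_5	island_b
pair1_pop2_6	island_b
pair1_pop2_7	island_b
pair1_pop2_8	island_b
pair1_pop2_9	island_b
pair1_pop2_10	island_b
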