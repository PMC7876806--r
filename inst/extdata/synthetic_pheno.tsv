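sample_id	phenotype
sample1	1
sample2	1
sample3	1
sample4	1
sample5	1
sample6	1
sample7	1
sample8	1
sample9	0
sample10	0
sample11	0
sample12	0
sample13	0
sample14	0
sample15	0
sample16	0
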