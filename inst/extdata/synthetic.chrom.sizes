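chr1	240000000
chr2	235000000
chr3	225000000
chr4	215000000
chr5	205000000
chr6	195000000
chr7	185000000
chr8	175000000
chr9	165000000
chr10	155000000
chr11	150000000
chr12	140000000
chr13	130000000
chr14	120000000
chr15	110000000
chr16	100000000
chr17	95000000
chr18	90000000
chr19	85000000
chr20	80000000
chr21	75000000
chr22	70000000
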