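count	freq	cdr3nt	cdr3aa	v	d	j
79	0.1975	TGTGTCTGTATGGTCAACTTTAATAATGCCCAGGGTCACTTT	CVCMVNFNNAQGHF	TRBV29	TRBD2	TRBJ1-6
33	0.0825	TGTGGCTGTATGCCCAACACTCTTATGCAAATCCCTTACGACTACTTT	CGCMPNTLMQIPYDYF	TRBV9	TRBD2	TRBJ1-2
8	0.02	TGTCCCAATGCTGCTAATGTCAACGTTGAGGATGATTGGCACATGTTT	CPNAANVNVEDDWHMF	TRBV9	TRBD1	TRBJ1-4
41	0.1025	TGTCGCCCCTCCTGTCTTTCTAAGCAGTCTACTAAGTTT	CRPSCLSKQSTKF	TRBV14	TRBD1	TRBJ2-5
43	0.1075	TGTATCTTTGAAATGTGTAAATTCTTT	CIFEMCKFF	TRBV7	TRBD1	TRBJ2-4
20	0.05	TGTATGATGATGCTGGACGGCGACTTT	CMMMLDGDF	TRBV29	TRBD2	TRBJ1-4
34	0.085	TGTGTCCGTAAGTCTGGCGAGACTGTTGTCTTT	CVRKSGETVVF	TRBV20	TRBD1	TRBJ1-3
17	0.0425	TGTCTGCCCTGGATGCATGATCCTTGGGCCAAGTTCTGTTTT	CLPWMHDPWAKFCF	TRBV6	TRBD1	TRBJ1-1
15	0.0375	TGTAACTATAACTGTTTTATTTGTTGGTTT	CNYNCFICWF	TRBV27	TRBD2	TRBJ2-7
16	0.04	TGTGGCTGGTCTAAGTGTCGCGTTTCTTACCCCTTT	CGWSKCRVSYPF	TRBV13	TRBD2	TRBJ1-6
22	0.055	TGTTATTACTGGATGCCTTTTGTCTTCCACGAAAAGCGTCTGCCTCGCTTT	CYYWMPFVFHEKRLPRF	TRBV13	TRBD2	TRBJ2-1
72	0.18	TGTCGTACCTGTCCTGTTATTTACGCCTGGCAACATTTT	CRTCPVIYAWQHF	TRBV3	TRBD2	TRBJ2-3
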