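duplicate_count	junction	junction_aa	v_call	d_call	j_call
79	TGTGTCTGTATGGTCAACTTTAATAATGCCCAGGGTCACTTT	CVCMVNFNNAQGHF	TRBV29	TRBD2	TRBJ1-6
33	TGTGGCTGTATGCCCAACACTCTTATGCAAATCCCTTACGACTACTTT	CGCMPNTLMQIPYDYF	TRBV9	TRBD2	TRBJ1-2
8	TGTCCCAATGCTGCTAATGTCAACGTTGAGGATGATTGGCACATGTTT	CPNAANVNVEDDWHMF	TRBV9	TRBD1	TRBJ1-4
41	TGTCGCCCCTCCTGTCTTTCTAAGCAGTCTACTAAGTTT	CRPSCLSKQSTKF	TRBV14	TRBD1	TRBJ2-5
43	TGTATCTTTGAAATGTGTAAATTCTTT	CIFEMCKFF	TRBV7	TRBD1	TRBJ2-4
20	TGTATGATGATGCTGGACGGCGACTTT	CMMMLDGDF	TRBV29	TRBD2	TRBJ1-4
34	TGTGTCCGTAAGTCTGGCGAGACTGTTGTCTTT	CVRKSGETVVF	TRBV20	TRBD1	TRBJ1-3
17	TGTCTGCCCTGGATGCATGATCCTTGGGCCAAGTTCTGTTTT	CLPWMHDPWAKFCF	TRBV6	TRBD1	TRBJ1-1
15	TGTAACTATAACTGTTTTATTTGTTGGTTT	CNYNCFICWF	TRBV27	TRBD2	TRBJ2-7
16	TGTGGCTGGTCTAAGTGTCGCGTTTCTTACCCCTTT	CGWSKCRVSYPF	TRBV13	TRBD2	TRBJ1-6
22	TGTTATTACTGGATGCCTTTTGTCTTCCACGAAAAGCGTCTGCCTCGCTTT	CYYWMPFVFHEKRLPRF	TRBV13	TRBD2	TRBJ2-1
72	TGTCGTACCTGTCCTGTTATTTACGCCTGGCAACATTTT	CRTCPVIYAWQHF	TRBV3	TRBD2	TRBJ2-3
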