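site	sample_id	motif	window_lo	window_hi	haplogroup	status
Tell Halula	H3	16293C	16256	16369	R0	validated
Tell Halula	H4	16311C	16126	16369	K	validated
Tell Halula	H7	16311C	16126	16369	K	validated
Tell Halula	H8	16223T	16126	16369	L3	validated
Tell Halula	H70	16356C	16126	16369	N*	validated
Tell Halula	H68	16294T	16256	16369	H	validated
Tell Halula	H53	CRS	16126	16256	HV	provisional
Tell Halula	H49	16256T	16126	16369	H	validated
Tell Halula	H25	16224C 16311C	16126	16369	K	validated
Tell Halula	H28	16311C	16256	16369	U*	validated
Tell Ramad	R64-4II	16293C	16256	16369	R0	validated
Tell Ramad	R65-14	16224C 16311C 16366T	16126	16369	K	validated
Tell Ramad	R69(2)	16293C	16126	16369	R0	validated
Tell Ramad	R65-C8-SEB	16224C 16311C 16366T	16126	16369	K	validated
Tell Ramad	R65-1S	16224C 16311C 16366T	16126	16369	K	validated
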