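sample_id	position	base	validated
H3	7028	T	TRUE
H3	12308	A	TRUE
H3	14766	T	TRUE
H3	10873	T	TRUE
H3	10550	G	FALSE
H3	12705	C	TRUE
H4	7028	T	TRUE
H4	12308	G	TRUE
H4	10550	G	TRUE
H7	7028	T	TRUE
H7	12308	G	TRUE
H7	10550	G	TRUE
H8	7028	T	TRUE
H8	12308	A	TRUE
H8	14766	T	FALSE
H8	10873	C	TRUE
H8	10550	A	TRUE
H8	10398	A	TRUE
H8	10400	C	TRUE
H70	7028	T	TRUE
H70	12308	A	TRUE
H70	14766	T	TRUE
H70	10873	T	TRUE
H70	10550	A	TRUE
H70	12705	T	TRUE
H70	4646	T	TRUE
H68	7028	C	TRUE
H53	7028	T	FALSE
H53	12308	A	FALSE
H53	12705	C	FALSE
H49	7028	C	TRUE
H49	12308	A	FALSE
H49	10550	A	FALSE
H49	12705	C	FALSE
H25	7028	T	FALSE
H25	12308	G	TRUE
H25	10550	G	TRUE
H28	7028	T	FALSE
H28	12308	G	TRUE
H28	10550	A	TRUE
R64-4II	7028	T	TRUE
R64-4II	12308	A	TRUE
R64-4II	14766	T	TRUE
R64-4II	10550	A	TRUE
R64-4II	12705	C	TRUE
R65-14	7028	T	FALSE
R65-14	12308	G	TRUE
R65-14	14766	T	FALSE
R65-14	10550	G	TRUE
R69(2)	7028	T	TRUE
R69(2)	12308	A	TRUE
R69(2)	10873	T	TRUE
R69(2)	12705	C	TRUE
R65-C8-SEB	7028	T	FALSE
R65-C8-SEB	12308	G	TRUE
R65-1S	7028	T	FALSE
R65-1S	12308	G	FALSE
R65-1S	10550	G	TRUE
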