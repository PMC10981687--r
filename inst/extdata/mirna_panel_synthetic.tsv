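mirna	conserved	expressed_embryo_or_l1	intronic_same_strand	previously_studied	family
let-7	TRUE	TRUE	FALSE	TRUE	let-7-fam
miR-1	TRUE	TRUE	FALSE	TRUE	miR-1
miR-2	TRUE	TRUE	FALSE	FALSE	miR-2-fam
miR-34	TRUE	TRUE	FALSE	FALSE	miR-34
miR-35	TRUE	TRUE	FALSE	TRUE	miR-35
miR-43	TRUE	TRUE	FALSE	FALSE	miR-2-fam
miR-44	TRUE	TRUE	FALSE	FALSE	miR-44
miR-45	TRUE	TRUE	FALSE	FALSE	miR-45
miR-46	TRUE	TRUE	FALSE	FALSE	miR-46
miR-47	TRUE	TRUE	FALSE	FALSE	miR-47
miR-48	TRUE	TRUE	FALSE	FALSE	let-7-fam
miR-49	TRUE	TRUE	FALSE	FALSE	miR-49
miR-50	TRUE	TRUE	FALSE	FALSE	miR-50
miR-51	TRUE	TRUE	FALSE	FALSE	miR-51
miR-52	TRUE	TRUE	FALSE	FALSE	miR-52
miR-54	TRUE	TRUE	FALSE	FALSE	miR-54-fam
miR-55	TRUE	TRUE	FALSE	FALSE	miR-54-fam
miR-56	TRUE	TRUE	TRUE	FALSE	miR-54-fam
miR-57	TRUE	TRUE	FALSE	TRUE	miR-57
miR-58	TRUE	TRUE	TRUE	FALSE	miR-58-fam
miR-59	TRUE	TRUE	FALSE	FALSE	miR-59
miR-60	TRUE	TRUE	FALSE	FALSE	miR-60
miR-61	TRUE	TRUE	FALSE	FALSE	miR-61
miR-67	TRUE	TRUE	TRUE	FALSE	miR-67
miR-71	TRUE	TRUE	TRUE	TRUE	miR-71
miR-72	TRUE	TRUE	FALSE	FALSE	miR-72
miR-73	TRUE	TRUE	FALSE	FALSE	miR-73
miR-74	TRUE	TRUE	FALSE	FALSE	miR-74
miR-75	TRUE	TRUE	FALSE	FALSE	miR-75
miR-76	TRUE	TRUE	TRUE	FALSE	miR-76
miR-77	TRUE	TRUE	FALSE	FALSE	miR-77
miR-79	TRUE	TRUE	FALSE	FALSE	miR-79
miR-80	TRUE	TRUE	FALSE	FALSE	miR-58-fam
miR-81	TRUE	TRUE	FALSE	FALSE	miR-58-fam
miR-82	TRUE	TRUE	FALSE	FALSE	miR-58-fam
miR-83	TRUE	TRUE	FALSE	FALSE	miR-83
miR-84	TRUE	TRUE	FALSE	FALSE	let-7-fam
miR-86	TRUE	TRUE	TRUE	FALSE	miR-86
miR-87	TRUE	TRUE	TRUE	FALSE	miR-87
miR-90	TRUE	TRUE	TRUE	FALSE	miR-90
miR-124	TRUE	TRUE	TRUE	TRUE	miR-124
miR-153	TRUE	TRUE	FALSE	FALSE	miR-153
miR-228	TRUE	TRUE	FALSE	FALSE	miR-228
miR-230	TRUE	TRUE	FALSE	FALSE	miR-230
miR-231	TRUE	TRUE	FALSE	FALSE	miR-231
miR-232	TRUE	TRUE	FALSE	TRUE	miR-232
miR-233	TRUE	TRUE	FALSE	FALSE	miR-233
miR-234	TRUE	TRUE	FALSE	FALSE	miR-234
miR-235	TRUE	TRUE	FALSE	FALSE	miR-235
miR-236	TRUE	TRUE	FALSE	FALSE	miR-236
miR-237	TRUE	TRUE	FALSE	FALSE	miR-237
miR-238	TRUE	TRUE	FALSE	FALSE	miR-238
miR-239	TRUE	TRUE	FALSE	FALSE	miR-239
miR-240	TRUE	TRUE	FALSE	FALSE	miR-240
miR-241	TRUE	TRUE	FALSE	FALSE	let-7-fam
miR-242	TRUE	TRUE	FALSE	FALSE	miR-242
miR-244	TRUE	TRUE	FALSE	FALSE	miR-244
miR-245	TRUE	TRUE	FALSE	FALSE	miR-245
miR-252	TRUE	TRUE	FALSE	FALSE	miR-252
miR-259	TRUE	TRUE	FALSE	FALSE	miR-259
miR-795	TRUE	TRUE	FALSE	FALSE	miR-795
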