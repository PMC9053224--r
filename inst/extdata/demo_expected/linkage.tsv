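node_a	node_b	height
-54	-30	0.12568816
-42	-18	0.14036625
-59	-45	0.14661922
-55	-39	0.15207474
-53	-29	0.15939865
-40	-34	0.17583365
-49	-19	0.17832063
-37	-25	0.17879818
-60	-12	0.1797321
-50	-43	0.18971241
-46	-16	0.21396746
-51	-27	0.22036619
-33	-21	0.2349091
-6	9	0.24187589
-48	-24	0.25037827
-56	-41	0.26304529
-38	-26	0.28588139
-31	-7	0.29687969
-52	-15	0.30365625
-32	-8	0.30451255
-44	-14	0.3053644
-23	5	0.31916703
-36	2	0.32230919
-58	-17	0.32708207
7	18	0.32815812
-57	-9	0.32870161
-35	-11	0.33534648
-5	22	0.38093497
-47	27	0.38148778
-28	11	0.38148937
13	26	0.42384398
-20	-2	0.43209112
-1	25	0.43218259
-22	-10	0.44551685
20	21	0.45333831
-4	6	0.50064169
-13	33	0.50211549
14	15	0.52204892
28	29	0.52263719
-3	8	0.54322245
17	35	0.55550325
1	23	0.63178447
32	41	0.64512371
4	31	0.6617431
12	19	0.66365625
30	34	0.68236302
10	24	0.72963788
44	45	0.83574203
37	40	0.86964687
36	46	0.87465941
3	48	0.92738642
38	42	0.97812007
16	39	0.98607509
47	50	1.1117115
49	51	1.5349222
53	54	1.6126186
52	56	1.8488044
43	55	1.8529421
57	58	2.1758984
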