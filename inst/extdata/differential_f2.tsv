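accession	log2_lh	p_value	coverage
Q3TZN9	+	0.000	26.9
Q91YW3	3.83	0.000	20.0
P01899	2.32	0.000	12.4
Q810U4	2.28	0.000	7.1
A2AR26	2.09	0.000	11.7
P63085	2.09	0.000	30.2
Q61213	2.02	0.000	4.6
P03975	1.99	0.000	36.6
P01900	1.80	0.000	23.3
Q3UT74	1.67	0.000	8.4
P26955	1.48	0.001	8.4
P97333	1.38	0.001	15.0
Q921H8	1.38	0.001	16.0
Q61207	1.33	0.002	7.5
Q8C166	1.32	0.002	6.3
Q9JLZ8	1.31	0.002	7.8
Q9D620	1.31	0.002	24.5
Q05910	1.29	0.003	7.7
Q99LS5	1.28	0.003	4.5
P12265	1.22	0.005	21.0
Q3TYD6	1.13	0.009	8.2
O54782	1.08	0.012	7.1
Q9DC29	1.06	0.013	14.8
Q9D1R9	1.05	0.015	23.1
P01902	0.99	0.021	26.4
P12970	0.98	0.023	33.1
Q09200	0.98	0.023	20.1
Q924S8	0.97	0.024	11.3
P31996	0.97	0.025	5.5
P35979	0.92	0.033	15.2
Q61033	0.88	0.041	4.2
P42082	0.87	0.044	22.3
Q61735	0.87	0.044	8.9
P62270	0.85	0.048	17.1
P58681	-3.89	0.000	15.0
P24063	-2.37	0.000	8.1
Q3UQJ7	-2.24	0.000	13.1
Q8BNL1	-2.07	0.000	6.0
P62814	-2.00	0.000	35.4
Q8BVE3	-1.98	0.000	25.3
P20152	-1.94	0.000	30.0
P50516	-1.92	0.000	48.8
P50518	-1.91	0.000	34.5
Q9Z1G3	-1.90	0.000	24.1
A1L314	-1.77	0.000	8.4
Q69ZN7	-1.76	0.000	32.6
P57746	-1.49	0.000	29.6
P47738	-1.41	0.000	37.0
O89001	-1.34	0.001	5.3
Q3U829	-1.29	0.001	2.5
Q8R4Y4	-1.12	0.005	1.8
P70290	-1.12	0.005	10.1
Q80VQ0	-1.11	0.005	22.6
Q7TPR4	-1.06	0.008	26.9
P17439	-1.05	0.008	15.1
Q9CPN8	-0.96	0.015	26.4
Q99K70	-0.93	0.019	8.8
P30204	-0.92	0.020	32.1
Q03265	-0.92	0.020	32.7
P60122	-0.92	0.020	9.0
O35474	-0.90	0.023	5.8
Q91WB7	-0.90	0.023	10.6
P55302	-0.87	0.028	9.7
Q91VR2	-0.84	0.034	8.4
Q8BFR5	-0.82	0.038	5.8
Q8BIJ7	-0.82	0.040	13.3
Q3UH76	-0.80	0.043	17.8
O08599	-0.80	0.043	9.9
Q9WV54	-0.79	0.046	18.3
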