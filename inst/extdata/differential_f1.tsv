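accession	log2_lh	p_value	coverage
Q3TZN9	+	0.000	34.9
Q91YW3	4.48	0.000	20.2
Q3TYT8	3.34	0.000	6.1
P01899	3.06	0.000	12.4
Q3U651	2.44	0.000	5.1
P01900	2.16	0.000	37.5
Q91VK4	2.00	0.000	20.4
P28798	1.99	0.000	13.9
Q810U4	1.95	0.000	13.6
P10404	1.90	0.000	6.2
Q61207	1.81	0.001	11.3
P12023	1.75	0.001	12.3
P97333	1.64	0.002	22.0
O09126	1.63	0.002	8.7
Q80V26	1.58	0.003	6.2
P06797	1.56	0.004	34.4
Q61469	1.53	0.004	5.7
Q8K482	1.48	0.006	8.3
P03975	1.48	0.006	19.4
Q9D620	1.33	0.013	7.6
P42082	1.32	0.014	20.4
Q60751	1.29	0.016	8.3
Q05910	1.28	0.017	11.6
Q8BWW9	1.27	0.017	14.3
P01902	1.25	0.019	29.3
P27512	1.21	0.023	12.8
P10923	1.21	0.024	15.0
P16675	1.20	0.025	14.1
A2AR26	1.18	0.027	7.9
O89103	1.18	0.028	30.0
O89017	1.16	0.030	17.7
O35474	1.14	0.033	9.6
P35951	1.12	0.036	12.0
P58681	-4.41	0.000	11.0
P47738	-2.74	0.000	24.1
P53026	-2.61	0.000	18.9
A1L314	-2.14	0.000	18.0
Q03265	-2.07	0.000	28.2
Q61549	-1.78	0.001	6.8
P24063	-1.72	0.002	21.8
Q3TVQ0	-1.61	0.003	4.1
Q7TPV4	-1.54	0.004	11.0
Q8CGK3	-1.54	0.004	4.0
P26443	-1.42	0.009	9.5
Q3TFD0	-1.42	0.009	22.8
P51675	-1.42	0.009	8.2
P63038	-1.37	0.012	36.8
Q99KI0	-1.37	0.012	11.2
P38647	-1.37	0.012	8.0
Q6P5F7	-1.37	0.012	4.8
Q8CGC6	-1.26	0.020	4.0
Q91VE6	-1.16	0.033	13.2
P20152	-1.13	0.038	67.4
Q69ZN7	-1.12	0.039	54.2
P21956	-1.11	0.040	21.8
P57746	-1.11	0.040	18.6
Q60932	-1.09	0.045	39.9
Q3TJG0	-1.07	0.049	8.1
P50516	-1.07	0.049	42.5
Q9DBG7	-1.07	0.049	8.5
Q8JZR0	-1.07	0.049	4.1
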