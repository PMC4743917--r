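y	x1	x2	x3	x4	x5	x6
-0.316	-0.0804	-0.811	0.0861	0.5344	1.9409	1.4507
-1.1085	-0.6937	0.0778	0.503	0.7999	-0.7326	0.6437
-0.2022	-0.859	-0.4052	0.8907	-0.5641	1.1057	-1.4055
2.7568	1.5007	-2.9596	0.1724	0.5178	0.2332	-1.3908
-0.954	-0.3881	-0.1223	1.3325	0.4146	0.4849	0.2983
0.6247	0.0981	-0.926	-1.0164	1.3781	-0.5883	0.1778
-0.5253	-1.4235	0.5999	-0.1176	1.6089	-0.0467	0.9894
0.1618	-0.9589	-1.5903	-1.4242	-0.5521	0.3923	0.7351
1.1425	-0.5146	-0.0187	-0.8558	1.1635	-0.5861	0.6095
2.0535	-1.2674	-1.3801	0.162	-0.1094	-0.173	0.4202
-0.0974	-0.6831	0.3831	0.915	0.0567	-0.0952	-1.3247
0.7842	0.6835	-0.469	0.6002	0.3409	-3.1215	-1.8482
-3.9705	-2.2887	0.8414	0.1605	1.0258	0.7629	-0.4007
0.6245	-0.1017	-0.6476	-0.9356	-0.334	1.5615	-0.8743
1.5221	0.0152	-0.7443	-1.4483	-0.549	0.7778	-1.0106
1.6159	0.5914	0.4581	0.9795	0.2537	0.0061	1.2448
2.7108	0.8007	-2.8516	1.1852	0.3743	-1.5285	2.102
-2.1617	1.2327	0.2094	-1.2439	0.2489	2.373	0.6717
-2.9145	-0.3092	1.439	-0.4384	-0.8929	1.7693	-0.3035
-3.7374	-0.9452	-0.2514	1.5957	-0.1067	1.0178	1.2296
-2.8467	-1.1158	1.7357	-0.5229	0.3293	-0.9117	-2.0814
0.7255	-0.7052	-1.1145	0.6676	-0.4841	-0.1691	0.3235
3.8413	0.9931	-1.5282	-2.1293	1.1164	0.398	-0.3067
4.2053	0.2942	-0.9962	-1.9533	-0.0056	1.9468	-0.4138
2.001	2.1049	0.0626	0.8042	-0.8299	-0.8363	1.099
-1.2059	1.9205	1.6951	-1.0899	2.1916	0.6528	-1.2339
0.2835	0.5428	0.0597	0.2688	0.9333	0.3379	0.0799
-1.4687	-0.8643	0.4794	-0.2127	-0.2398	-1.4194	-0.0778
-0.9357	0.4162	1.7042	0.8701	-0.8912	1.4479	-0.1132
1.8595	0.6501	-0.0776	-0.36	-1.3796	0.7278	0.8484
-0.9996	0.1449	1.4437	0.8858	-0.3611	-0.8502	-0.4472
-0.2319	-1.1836	0.265	1.3189	-0.4471	1.9962	1.2902
0.8998	1.3975	1.1587	1.836	-1.0648	-1.2225	-1.1177
-0.6556	-0.5118	0.4268	-0.7957	0.2525	-0.113	-0.2101
0.1891	-0.3257	1.9032	0.043	0.0052	3.0228	-0.184
0.1883	-0.2518	-0.3388	-0.4098	2.1264	-0.8022	0.2932
0.6388	0.2136	1.2448	-0.8188	0.4397	-0.6636	-0.2467
0.4079	0.8666	0.2413	2.2297	0.8093	-0.8196	0.6657
-0.3463	-0.2095	1.0932	1.4837	-0.5535	-0.1827	-1.7143
1.9292	1.4856	1.3827	-0.5964	-2.3134	1.0652	-0.352
0.7751	0.4996	-1.2949	1.2597	0.0908	0.1364	0.2958
-1.3011	-1.661	-0.5362	-0.2018	2.2685	2.3511	1.1005
-1.8251	0.4724	0.7749	-1.0242	0.4369	0.1766	-1.237
-1.9637	-1.3266	-0.5678	0.1832	-1.2957	-0.32	0.1149
1.7418	0.3163	-1.8569	0.4791	0.1834	-0.0925	-0.2296
-1.28	-0.3102	0.7218	0.2041	1.0329	0.2775	-0.88
1.3524	-0.0625	-1.2559	-0.8609	1.0012	1.2387	1.3597
-4.3239	-0.5787	1.8686	1.2711	1.6002	-0.0924	1.9852
1.1407	-0.2193	-1.7126	-0.2546	-0.4861	1.1633	-0.8468
-1.756	-0.8741	0.9776	-0.6495	-0.5619	-0.3563	0.9673
0.1199	0.5639	0.5108	-0.7222	0.6339	-0.441	-0.4676
-1.0167	0.0172	1.4455	2.2288	1.437	-0.5587	1.3093
1.278	0.9296	0.5551	-1.3369	-1.689	-0.7471	0.2861
-0.1305	-1.9969	-0.3678	-0.9407	0.6396	0.2799	-0.6208
-0.5625	-1.1355	0.8395	0.0588	0.6565	0.6118	-0.9115
-1.5831	1.6613	2.3197	-0.728	0.9839	-1.1681	-0.074
-0.9389	-2.1669	0.1233	-0.3242	-0.6411	-1.0529	0.0254
-1.2306	0.614	0.1201	-1.1347	-1.4702	-0.0582	-1.1884
-1.8727	-1.696	0.5681	0.449	-0.9112	0.2739	-0.618
0.1593	-1.0346	-0.7664	0.6686	0.5487	1.4665	1.029
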