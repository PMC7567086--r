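A	C	G	T
-7.730	2.252	-7.730	-7.730
-8.208	2.273	-8.208	-8.208
2.042	-8.495	0.800	-8.495
-8.327	1.773	-8.327	-8.327
-7.858	1.712	-7.858	-7.858
1.916	-7.520	-7.520	-7.520
-7.623	-7.623	2.197	-7.623
-8.073	-8.073	2.297	-8.073
-8.456	0.700	-8.456	2.124
-8.420	-8.420	1.837	-8.420
-7.998	-7.998	1.700	-7.998
-7.578	1.839	-7.578	-7.578
2.126	-7.546	-7.546	-7.546
-7.932	-7.932	2.297	-7.932
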