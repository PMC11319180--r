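exposure	outcome	analysis	p	or	ci_low	ci_high
CE 20:4;0	ICH	discovery	0.047	0.94	0.88	0.999
LPC 20:4;0	ICH	discovery	0.034	0.91	0.83	0.99
PC 16:0;0_20:4;0	ICH	discovery	0.040	0.93	0.86	0.996
PC 17:0;0_18:2;0	ICH	discovery	0.049	1.16	1.001	1.35
PC 18:0;0_18:2;0	ICH	discovery	0.024	1.17	1.02	1.34
PC 18:0;0_20:4;0	ICH	discovery	0.016	0.92	0.87	0.99
PC 18:1;0_20:4;0	ICH	discovery	0.017	0.91	0.84	0.98
PE 16:0;0_18:2;0	ICH	discovery	0.002	1.14	1.05	1.24
PE 16:0;0_20:4;0	ICH	discovery	0.03	1.10	1.01	1.19
SM 36:2;2	ICH	discovery	0.003	0.79	0.67	0.93
SM 38:2;2	ICH	discovery	0.028	0.88	0.78	0.99
CE 16:1;0	SAH	discovery	0.02	0.86	0.76	0.98
CE 18:1;0	SAH	discovery	0.049	0.80	0.64	0.999
CE 18:3;0	SAH	discovery	0.025	0.82	0.69	0.98
CE 20:3;0	SAH	discovery	0.0002	0.77	0.66	0.88
PC 18:1;0_20:4;0	SAH	discovery	0.047	0.82	0.68	0.997
PE 18:0;0_20:4;0	SAH	discovery	0.017	0.90	0.82	0.98
CE 20:4;0	ICH	meta	0.006	0.929	0.881	0.979
LPC 20:4;0	ICH	meta	0.001	0.904	0.850	0.961
PC 16:0;0_20:4;0	ICH	meta	0.007	0.916	0.858	0.977
PC 18:0;0_20:4;0	ICH	meta	<0.001	0.914	0.866	0.964
PC 18:1;0_20:4;0	ICH	meta	<0.001	0.892	0.835	0.954
SM 36:2;2	ICH	meta	<0.001	0.766	0.676	0.868
SM 38:2;2	ICH	meta	0.004	0.859	0.774	0.954
PC 17:0;0_18:2;0	ICH	meta	<0.001	1.232	1.092	1.391
PC 18:0;0_18:2;0	ICH	meta	0.002	1.179	1.065	1.306
PE 16:0;0_18:2;0	ICH	meta	<0.001	1.147	1.079	1.219
PE 16:0;0_20:4;0	ICH	meta	0.006	1.088	1.024	1.155
CE 16:1;0	SAH	meta	0.015	0.878	0.792	0.975
CE 18:3;0	SAH	meta	0.035	0.848	0.727	0.989
CE 20:3;0	SAH	meta	<0.001	0.786	0.704	0.877
PC 18:1;0_20:4;0	SAH	meta	0.002	0.794	0.689	0.916
PE 18:0;0_20:4;0	SAH	meta	0.003	0.905	0.846	0.967
CE 18:1;0	SAH	meta	0.775	0.951	0.674	1.342
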