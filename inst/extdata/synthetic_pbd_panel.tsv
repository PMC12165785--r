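variant_id	role	mean_day12_untreated	mean_day12_parpi	mean_day12_cisplatin	mean_day12_mmc	faf_max	maf_max	bayesdel_noaf	spliceai_delta	asserted_codes	prior_class
T10P	query	85.4	77.9	77.7	99.8	NA	NA	0.169	0.078		VUS
T10I	query	84.1	86.2	79.5	94.9	NA	1.77e-05	0.051	0.061		VUS
T10K	query	97	30.1	38	82.8	NA	NA	0.051	0.074		VUS
F11L_c.31T>C	query	97.3	82.1	85.3	85.4	6.96e-05	8.35e-05	0.084	0.066		VUS
F11V	query	89	78.2	97	99	NA	NA	0.113	0.055		VUS
F11C	query	78.8	83.6	100.8	93.8	NA	1.39e-05	0.14	0.043		VUS
F11L_c.33T>G	query	90.3	101.4	87.7	89	5.7e-05	6.84e-05	0.133	0.067		VUS
F12S	query	84.4	80.6	90.5	96.5	NA	NA	0.055	0.075		VUS
E13K	query	77.8	100.9	85.8	84.2	NA	1.54e-05	0.025	0.005		VUS
E13V	query	99	98.1	100.5	100.4	4.18e-05	5.02e-05	0.024	0.004		VUS
E13D	query	77.1	75.7	99.9	83.2	NA	NA	0.125	0.027		VUS
I14V	query	104.8	78.8	104.6	90	NA	1.36e-05	0.086	0.019		VUS
I14N	query	103.7	90.9	83.2	76.5	5e-05	6e-05	0.029	0.019		VUS
I14M	query	84.7	93.3	96.1	98.9	NA	NA	0.049	0.001		VUS
F15L	query	103.2	76.3	78.8	87.9	NA	3.45e-06	0.098	0.034		VUS
F15C	query	76.2	100.2	100	91	8.11e-05	9.73e-05	0.098	0.003		VUS
K16R	query	101.3	101.7	93.6	87.3	NA	NA	0.165	0.058		VUS
T17I	query	85.8	98.5	104.9	86.2	NA	1.16e-05	0.028	0.006		VUS
C19R	query	84.5	95.1	100.7	101.1	3.79e-05	4.55e-05	0.028	0.043		VUS
C19Y	query	93.7	96.3	103.1	100.1	NA	NA	0.019	0.066		VUS
C19F	query	81.2	100	103.2	99	NA	1.57e-05	0.114	0.016		VUS
A22=_c.66A>C	query	81.4	43.3	42.7	7.4	NA	NA	0.117	0.45	PS1_splicing:moderate	VUS
A22=_c.66A>G	query	91.3	31.3	42.6	10.9	NA	NA	0.071	0.45	PS1_splicing:moderate	VUS
A22=_c.66A>T	query	93.1	35.4	31.6	10.6	NA	NA	0.013	0.45	PS1_splicing:moderate	VUS
D23H	query	4.4	11.3	2	4.5	NA	NA	0.128	0.95	PVS1_RNA:strong	VUS
D23G	query	100.7	81.6	92.3	85.8	5.53e-05	6.64e-05	0.141	0.046		VUS
D23V	query	91.7	79.2	101.4	94.7	NA	NA	0.095	0.07		VUS
L24V	query	75.3	78.4	93	104.7	NA	1.16e-05	0.13	0.062		VUS
L24F	query	92.7	90.8	79.4	85.4	4.95e-05	5.94e-05	0.081	0.068		VUS
G25R	query	81.6	75	80.2	43.7	NA	NA	0.036	0.012		VUS
G25E	query	87	89.6	84.7	86.9	NA	NA	0.02	0.065		VUS
P26S	query	100.8	94.7	88.7	87.1	NA	1.64e-05	0.095	0.048		VUS
P26R	query	103.7	96.6	83.4	99.1	3.94e-05	4.73e-05	0.031	0.002		VUS
P26L	query	77.6	90.5	97.1	90.3	NA	NA	0.16	0.012		VUS
S28G	query	103.1	78.1	86.8	83.4	NA	8.12e-06	0.113	0.055		VUS
S28N	query	95.1	88.7	86	99.5	2.86e-05	3.43e-05	0.032	0.042		VUS
L29V	query	103.8	89.6	103.7	99.7	NA	NA	0.138	0.067		VUS
L29R	query	80.8	82.5	95	75.8	NA	1.14e-05	0.03	0.057		VUS
N30D	query	83.8	99.4	95.7	101.4	4.98e-05	5.98e-05	0.091	0.05		VUS
N30H	query	92	102.4	76.8	82.3	NA	NA	0.012	0.004		VUS
N30S	query	76.3	100.2	102	75.5	NA	1.24e-05	0.11	0.058		VUS
N30K	query	79.4	80.4	103.5	94.3	5.91e-05	7.09e-05	0.055	0.006		VUS
W31G	query	6.1	2.6	2.9	10.4	NA	NA	0.107	0.034		VUS
W31L	query	10.4	7.1	5.1	10.9	NA	NA	0.124	0.06		VUS
W31C	query	11.9	5.2	6.3	5.1	NA	NA	0.021	0.028		VUS
F32L_c.94T>C	query	92.2	87	98.2	86.3	NA	NA	0.036	0.025		VUS
F32L_c.96T>G	query	100.8	95	88.2	97.5	NA	1.79e-05	0.14	0.028		VUS
E33K	query	93.2	90.8	76.7	89.4	5.84e-05	7.01e-05	0.086	0.059		VUS
L35F	query	79.8	83.7	78.8	79.2	NA	NA	0.106	0.017		VUS
S36Y	query	102.9	86.1	78.5	76.6	NA	1.53e-05	0.1	0.008		VUS
S36F	query	92.7	103.2	82	80.8	2.82e-05	3.38e-05	0.161	0.038		VUS
S37A	query	75.6	79.6	97.5	79.1	NA	NA	0.055	0.024		VUS
S37L	query	98.6	104	86.2	87.8	NA	1.36e-05	0.126	0.037		VUS
E38K	query	95.4	100.1	88.9	90.6	6.87e-05	8.24e-05	0.149	0.008		VUS
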