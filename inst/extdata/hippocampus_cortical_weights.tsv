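area	location	mean_weight	sem	percent_all	percent_excl_mtl
TF	Lateral temporal cortex	7673	886	5.10	10.61
ProS	Medial parietal cortex (including posterior cingulate)	5483	784	3.64	7.58
V1	Early visual cortex (occipital)	5385	579	3.58	7.45
V2	Early visual cortex (occipital)	3840	462	2.55	5.31
POS1	Medial parietal cortex (including posterior cingulate)	3712	424	2.47	5.13
TGd	Temporal pole	3465	288	2.30	4.79
TGv	Temporal pole	3337	313	2.22	4.61
V3	Early visual cortex (occipital)	3079	450	2.05	4.26
TE2a	Lateral temporal cortex	2214	288	1.47	3.06
VMV2	Ventral stream visual cortex	2105	247	1.40	2.91
RSC	Medial parietal cortex (including posterior cingulate)	2063	121	1.37	2.85
VVC	Ventral stream visual cortex	1956	220	1.30	2.71
DVT	Medial parietal cortex (including posterior cingulate)	1939	335	1.29	2.68
POS2	Medial parietal cortex (including posterior cingulate)	1802	248	1.20	2.49
VMV1	Ventral stream visual cortex	1788	248	1.19	2.47
FFC	Ventral stream visual cortex	1670	172	1.11	2.31
V4	Early visual cortex (occipital)	1601	127	1.06	2.21
TE2p	Lateral temporal cortex	1288	198	0.86	1.78
V6	Dorsal stream visual cortex	1050	195	0.70	1.45
V3A	Dorsal stream visual cortex	1029	197	0.68	1.42
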