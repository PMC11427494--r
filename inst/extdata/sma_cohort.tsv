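code	sma_type	smn1_variation	smn2_copies	age_of_onset	age_range	scoliosis	spinal_fusion	wheelchair	rulm	hfmse
SMA_01	3	HD	3	16	10-19	no	no	no	37	61
SMA_02	3	HD	4	10	40-49	yes	no	no	33	33
SMA_03	2	HD	4	2	30-39	no	no	yes	15	8
SMA_05	3	HD	3	10	70-79	yes	no	yes	0	0
SMA_06	2	CHV	3	3	40-49	yes	no	yes	13	1
SMA_07	3	HD	3	15	50-59	yes	no	yes	32	23
SMA_08	2	HD	3	2	30-39	yes	no	yes	19	7
SMA_09	2	HD	3	3	40-49	yes	no	yes	8	0
SMA_10	3	CHV	3	7	30-39	yes	yes	yes	0	0
SMA_11	3	HD	3	7	40-49	no	no	no	37	44
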