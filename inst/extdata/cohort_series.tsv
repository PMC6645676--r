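series	patients	ruptured	mean_tts	sd_tts	MCA	ICA	AComm	PComm	PC
GSE13353	19	11	2.1	3.4	14	2	2	1	0
GSE15629	14	8	7.0	10.5	7	1	3	1	2
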