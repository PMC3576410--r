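family	segment	length	note
R1	S1	983	forced by copy-length system plus printed extremes 56 and 3922
R1	S2	3922	printed maximum segment length
R1	S3	56	printed minimum segment length
R1	S4	1541	determined by system
R1	S5	1276	determined by system
R1	S6	518	even split of determined sum S6+S7=1036 (split immaterial to anchors)
R1	S7	518	even split of determined sum S6+S7=1036
R1	S6*	673	printed; non-homologous variant occupying the S6 slot
R2	S1	4692	whole copy
R3	S1	6161	whole copy
R4	S1	3692	whole copy
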