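family	copy	begin	end	length	strand	identity	segments
R1	R1a	62,957	66,865	3,909	reverse	0.99	S3,S4,S5,S6,S7
R1	R1b	176,196	183,663	7,468	forward	0.99	S2,S3,S4,S5,S6*
R1	R1c	234,626	238,115	3,490	reverse	0.99	S4,S5,S6*
R1	R1d	255,146	261,647	6,502	forward	0.99	S1,S2,S3,S4
R1	R1e	353,867	362,680	8,814	forward	0.99	S1,S2,S3,S4,S5,S6,S7
R2	R2a	33,155	37,846	4,692	forward	0.99	S1
R2	R2b	276,715	281,406	4,692	forward	0.99	S1
R3	R3a	140,148	146,308	6,161	forward	0.99	S1
R3	R3b	205,656	211,816	6,161	reverse	0.99	S1
R4	R4a	241,273	244,964	3,692	forward	1.00	S1
R4	R4b	393,772	397,463	3,692	reverse	1.00	S1
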