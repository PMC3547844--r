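site	chrom	start	end	label
CLR1	3	123200	124000	CLR
CLR2	14	631600	632200	CLR
CLR3	6	221500	222200	CLR
CLR4	13	306300	307000	CLR
CLR5	9	356900	357600	CLR
CLR6	13	271700	272200	CLR
CLR7	4	1013700	1014300	CLR
CLR8	8	103900	104500	CLR
CLR9	5	140400	141000	CLR
CLR10	1	141500	142000	CLR
CLR11	8	125800	126400	CLR
CLR12	11	230600	231200	CLR
CLR13	4	465000	465800	CLR
CLR14	15	978300	979500	CLR
CLR15	11	518300	518900	CLR
CLR16	2	477000	477600	CLR
CLR17	13	253100	253800	CLR
CLR18	10	703200	704000	CLR
CLR19	7	483200	484000	CLR
CLR20	13	751300	751800	CLR
CLR21	5	305800	306400	CLR
CLR22	6	4600	5100	CLR
CLR23	11	666000	666600	CLR
LCNCR1	7	1000900	1001700	LCNCR
LCNCR2	6	253500	255300	LCNCR
LCNCR3	3	137600	139100	LCNCR
LCNCR4	15	159400	160400	LCNCR
LCNCR5	11	326000	327300	LCNCR
LCNCR6	7	883300	884000	LCNCR
LCNCR7	8	98300	99300	LCNCR
LCNCR8	16	550400	551900	LCNCR
LCNCR9	3	91300	92400	LCNCR
LCNCR10	7	507900	508600	LCNCR
LCNCR11	16	645600	646500	LCNCR
LCNCR12	11	163500	164600	LCNCR
LCNCR13	13	476000	477600	LCNCR
LCNCR14	5	291900	293000	LCNCR
LCNCR15	12	459700	460800	LCNCR
LCNCR16	12	232000	234500	LCNCR
LCNCR17	4	555700	556600	LCNCR
LCNCR18	15	779900	781200	LCNCR
LCNCR19	4	312700	314200	LCNCR
LCNCR20	12	370500	371000	LCNCR
LCNCR21	2	274100	281100	LCNCR
LCNCR22	13	220000	221200	LCNCR
LCNCR23	13	861100	861800	LCNCR
LCNCR24	8	451300	452700	LCNCR
LCNCR25	12	290100	292500	LCNCR
LCNCR26	11	345400	346500	LCNCR
LCNCR27	1	71700	73300	LCNCR
LCNCR28	2	373600	375800	LCNCR
LCNCR29	2	612500	614000	LCNCR
LCNCR30	12	369600	370400	LCNCR
LCNCR31	14	559200	559900	LCNCR
LCNCR32	4	600700	602200	LCNCR
LCNCR33	12	1064700	1065300	LCNCR
LCNCR34	15	29400	33900	LCNCR
LCNCR35	5	138400	138900	LCNCR
LCNCR36	4	461600	462600	LCNCR
LCNCR37	5	139000	139900	LCNCR
LCNCR38	12	837500	839300	LCNCR
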