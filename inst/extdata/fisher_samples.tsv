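sample	subspecies	population	accession
MP1	pacifica	S_California	GU121228
MP2	pacifica	S_California	GU121228
MP3	pacifica	S_California	GU121228
MP4	pacifica	N_California	GU121229
MP5	pacifica	N_California	GU121229
MP6	pacifica	N_California	GU121229
MP7	pacifica	N_California	GU121230
MP9	columbiana	Idaho_Montana	GU121231
MP10	columbiana	Idaho_Montana	GU121231
MP11	columbiana	British_Columbia	GU121232
MP12	columbiana	Idaho_Montana	GU121232
MP13	columbiana	Idaho_Montana	GU121232
MP14	columbiana	Idaho_Montana	GU121233
MP15	columbiana	Idaho_Montana	GU121233
MP16	columbiana	Idaho_Montana	GU121233
MP17	pennanti	Great_Lakes_MN	GU121234
MP18	pennanti	Great_Lakes_MN	GU121235
MP19	pennanti	Great_Lakes_WI	GU121236
MP20	pennanti	Great_Lakes_WI	GU121236
MP21	pacifica	S_California	GU121228
MP22	pacifica	S_California	GU121228
MP23	pacifica	S_California	GU121228
MP24	pacifica	S_California	GU121228
MP25	pacifica	N_California	GU121230
MP26	columbiana	British_Columbia	GU121231
MP27	columbiana	British_Columbia	GU121231
MP28	columbiana	British_Columbia	GU121237
MP29	columbiana	British_Columbia	GU121232
MP30	columbiana	British_Columbia	GU121232
MP31	columbiana	British_Columbia	GU121232
MP32	columbiana	Idaho_Montana	GU121232
MP34	pennanti	Great_Lakes_WI	GU121235
MP35	pennanti	Great_Lakes_WI	GU121235
MP36	pennanti	Great_Lakes_WI	GU121236
MP37	columbiana	British_Columbia	HQ705177
MP38	columbiana	British_Columbia	HQ705178
MP39	columbiana	British_Columbia	HQ705179
MP40	columbiana	British_Columbia	HQ705176
MP41	columbiana	Idaho_Montana	HQ705180
MP42	columbiana	Idaho_Montana	HQ705180
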