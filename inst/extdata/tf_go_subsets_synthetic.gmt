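GO0003677_DNA_binding	synthetic illustrative subset of DNA-binding mouse genes (not the full GO term)	Sox2	Sox9	Sox10	Ascl1	Dlx1	Dlx2	Dlx5	Dlx6	Emx1	Gsx2	Neurod1	Neurod6	Neurog2	Tbr1	Foxg1	Foxj1	Foxo3	Sp8	Sp9	Nr2e1	Nfix	Olig1	Olig2	Pax6	Hes1	Hes5	E2f8	Ctcf	Mcm2	Pcna
GO0140110_TF_activity	synthetic illustrative subset of transcription-regulator mouse genes (not the full GO term)	Sox2	Sox9	Ascl1	Dlx1	Dlx2	Emx1	Gsx2	Neurod1	Neurog2	Tbr1	Foxg1	Foxo3	Nr2e1	Nfix	Id1	Id2	Id3	Id4	Hopx	Hes1	Hes5	Olig2	Pax6	Rorb	Six3
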