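sample	karyotype	trisomy	ff_ordinary_pct	z_ordinary	ff_enriched_pct	z_enriched
FN1	47,XX,+21	chr21	5.6	2.41	15.6	11.92
FN2	47,XY,+18	chr18	8.5	-0.41	18.6	-1.05
FN3	47,XX,+21	chr21	4.8	1.14	11.4	5.076
FN4	47,XY,+21	chr21	12.4	0.791	26.4	2.16
FN5	47,XY,+18	chr18	7.1	0.313	15.2	1.687
FN6	47,XY,+18	chr18	5.1	1.713	11.8	4.01
FN7	47,XY,+21	chr21	11.2	0.163	18.8	-1.86
FN8	47,XY,+21	chr21	9.2	-0.56	19	1.096
FN9	47,XY,+21	chr21	7.5	-0.16	14.7	1.634
FN10	47,XY,+21	chr21	6.4	2.031	14.6	10.14
FN11	47,XY,+21	chr21	4.1	1.255	7.9	6.972
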