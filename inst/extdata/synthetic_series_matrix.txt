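!Series_title	"Synthetic watchful-waiting expression fixture"
!Series_geo_accession	"GSE00000"
!Sample_geo_accession	"GSM0001"	"GSM0002"	"GSM0003"	"GSM0004"	"GSM0005"	"GSM0006"
!Sample_characteristics_ch1	"outcome: Lethal"	"outcome: Indolent"	"outcome: Lethal"	"outcome: Indolent"	"outcome: Lethal"	"outcome: Unknown"
!Sample_characteristics_ch1	"followup_years: 4.2"	"followup_years: 14.5"	"followup_years: 6.1"	"followup_years: 12"	"followup_years: 2.8"	"followup_years: 1"
!Sample_characteristics_ch1	"gleason: 8"	"gleason: 6"	"gleason: 7"	"gleason: 6"	"gleason: 9"	"gleason: 7"
!Sample_characteristics_ch1	"erg: rearranged"	"erg: negative"	"erg: negative"	"erg: negative"	"erg: rearranged"	"erg: negative"
!Sample_characteristics_ch1	"batch: b1"	"batch: b1"	"batch: b2"	"batch: b2"	"batch: b1"	"batch: b2"
!series_matrix_table_begin
"ID_REF"	"GSM0001"	"GSM0002"	"GSM0003"	"GSM0004"	"GSM0005"	"GSM0006"
"g001"	9.0564	6.5400	7.3090	6.4491	9.2691	8.8014
"g002"	6.1530	4.3280	6.4584	7.2778	7.3869	8.5671
"g003"	7.5447	6.7421	8.1372	7.8727	7.1327	5.4952
"g004"	7.9493	8.8220	5.9099	9.0996	6.8187	9.7727
"g005"	7.6064	9.8428	4.9476	5.9091	5.2085	5.9998
"g006"	6.8408	6.3543	7.6492	8.9538	7.9180	7.1583
"g007"	9.2673	6.6141	5.7829	7.5038	6.6743	6.3666
"g008"	6.8580	4.3553	9.1662	8.5578	6.7259	6.8165
"g009"	10.0276	 7.6901	 6.3528	 8.3811	 8.4000	 7.2823
"g010"	6.9059	6.0400	7.9835	8.0813	8.2327	7.1787
"g011"	8.9573	7.6832	7.4829	5.4353	9.0882	6.9624
"g012"	10.4300	 8.0573	 5.8242	 6.8647	 6.2857	 7.1621
"g013"	4.9167	8.5527	9.3636	7.9353	7.9755	6.2718
"g014"	6.5818	6.0866	7.9643	5.5697	9.0867	6.2437
"g015"	6.8000	7.7574	7.1346	6.1858	5.3338	4.5084
"g016"	7.9539	4.4245	7.4148	7.8715	5.7088	6.4265
"g017"	6.5736	5.8233	8.0189	8.1523	5.3024	6.2310
"g018"	 3.0153	 5.7236	 7.1347	 7.6957	 4.8112	11.0528
"g019"	3.3393	3.3787	2.5104	5.6713	7.1200	4.9568
"g020"	8.9802	7.0542	7.4273	5.3503	7.9798	7.2059
!series_matrix_table_end
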