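key	kind	numerator	denominator	printed	digits	check	tolerance	note	citation
overall_success	rate	3806	4725	81	0	exact	0		Results: overall success of all sequenced cytology samples, 81% (3806/4725)
cb_success	rate	3616	4457	81	0	exact	0		Results: cell block success rate, 81% (3616/4457)
scfdna_success	rate	190	268	71	0	exact	0		Results: supernatant cfDNA rescue success rate, 71% (190/268)
canceled_requests	rate	146	4871	3	0	exact	0		Results: requests canceled before processing, 3% (146/4871)
cb_share_of_cohort	rate	4588	4871	94.2	1	exact	0		Results: cell block share of received samples, 94.2% (4588/4871)
scfdna_share_of_cohort	rate	283	4871	5.8	1	exact	0		Results: supernatant cfDNA share of received samples, 5.8% (283/4871)
internal_share	rate	3091	4871	63	0	exact	0		Table 1: internally processed samples, 63% (3091/4871)
external_share	rate	1780	4871	37	0	exact	0		Table 1: externally submitted samples, 37% (1780/4871)
contamination_all_sequenced	rate	246	4725	5.2	1	exact	0		Results: clinically relevant contamination (>=2%) among sequenced samples, 5.2% (246/4725)
contamination_excl_very_low_cov	rate	227	4725	4.8	1	exact	0		Results: contamination rate excluding <50x failures, 4.8% (227/4725)
cb_contamination_printed	rate	226	4725	4.7	1	flag_only	0	printed rate inconsistent with printed counts (226/4725 = 4.8%)	Results: cell block contamination printed as 4.7% (226/4725)
scfdna_contamination_printed	rate	1	4725	0.3	1	flag_only	0	printed rate inconsistent with printed counts (1/4725 = 0.0%)	Results: supernatant cfDNA contamination printed as 0.3% (1/4725)
surgical_contamination	rate	5	619	0.81	2	exact	0		Results: surgical samples with clinically relevant contamination, 0.81% (5/619)
str_confirmed_foreign_tissue	rate	65	189	34	0	exact	0		Results: contaminated optimal-coverage cell blocks traced to foreign tissue by STR, 34% (65/189)
cases_with_any_alteration	rate	3570	3806	93.8	1	exact	0		Results: successful cases harboring >=1 somatic alteration, 93.8% (3570/3806)
cb_with_any_alteration	rate	3394	3616	93.9	1	exact	0		Results: cell block cases with >=1 alteration, 93.9% (3394/3616)
scfdna_with_any_alteration	rate	176	190	92.6	1	exact	0		Results: supernatant cfDNA cases with >=1 alteration, 92.6% (176/190)
targetable_level1_3b	rate	2487	3806	65	0	exact	0		Results: cases with >=1 targetable (level 1/2/3A/3B) alteration, 65% (n = 2487)
resistance_r1	rate	93	3806	2	0	exact	0		Results: cases with a standard-care resistance (R1) mutation, 2% (n = 93)
cb_pairs_full_surgical_recovery	rate	266	482	55	0	exact	0		Results: cell block pairs recovering all surgical-sample alterations, 55% (266/482)
scfdna_pairs_full_surgical_recovery	rate	19	44	43	0	exact	0		Results: supernatant cfDNA pairs recovering all surgical alterations, 43% (19/44)
cb_paired_shared_mutations	rate	2789	5593	49.8	1	tolerance	0.1	recomputed 49.9 vs printed 49.8; source rounding convention unclear	Results: shared events in the cell block:surgical paired set, 49.8% (2789/5593)
vus_share_of_paired_mutations	rate	3468	5593	62	0	exact	0		Results: variants of unknown significance among paired-set mutations, 62% (3468/5593)
min_queryable_molecules	product	30	220.5	6615	0	exact	0	minimum input (ng) times lower 95% CI bound of target copies per ng	Methods: at the lowest 30 ng input, at least 6615 target molecules queried in 95% of cases
median_coverage_all	metadata	NA	NA	586	0	none	0	per-sample medians depend on protected raw data; reference only	Results: total median coverage of sequenced samples, 586x
median_coverage_cb	metadata	NA	NA	595	0	none	0	per-sample medians depend on protected raw data; reference only	Results: cell block median coverage, 595x
median_coverage_scfdna	metadata	NA	NA	263	0	none	0	per-sample medians depend on protected raw data; reference only	Results: supernatant cfDNA median coverage, 263x
median_yield_cb_ng	metadata	NA	NA	427.5	1	none	0	per-sample medians depend on protected raw data; reference only	Results: cell block median total DNA yield, 427.5 ng
median_yield_scfdna_ng	metadata	NA	NA	182.2	1	none	0	per-sample medians depend on protected raw data; reference only	Results: supernatant cfDNA median total DNA yield, 182.2 ng
copies_per_ng_mean	metadata	NA	NA	238	0	none	0	ddPCR-derived amplifiable target copies per ng of FFPE DNA	Methods: mean target copies per nanogram, 238
copies_per_ng_lo95	metadata	NA	NA	220.5	1	none	0	lower 95% CI bound of target copies per ng	Methods: 95% CI 220.5-255.5 copies/ng
copies_per_ng_hi95	metadata	NA	NA	255.5	1	none	0	upper 95% CI bound of target copies per ng	Methods: 95% CI 220.5-255.5 copies/ng
min_input_before_ng	metadata	NA	NA	50	0	none	0	minimum DNA input before the September 2021 threshold change	Methods: minimal total input of 50 ng (0.9 ng/uL x 55 uL)
min_input_after_ng	metadata	NA	NA	30	0	none	0	minimum DNA input after the September 2021 threshold change	Methods: minimal total input of 30 ng (0.54 ng/uL x 55 uL)
conc_threshold_before	metadata	NA	NA	0.9	2	none	0	minimum DNA concentration before September 2021	Methods: <0.9 ng/uL insufficient until 09/2021
conc_threshold_after	metadata	NA	NA	0.54	2	none	0	minimum DNA concentration from September 2021	Methods: threshold lowered to 0.54 ng/uL
total_received	metadata	NA	NA	4871	0	none	0	all cytology samples received for testing	Results: 4871 cytology tumor samples from 4633 patients
total_patients	metadata	NA	NA	4633	0	none	0	unique patients in the cohort	Results: 4871 cytology tumor samples from 4633 patients
total_alterations	metadata	NA	NA	30149	0	none	0	somatic alterations detected across successful cases	Results: 30,149 somatic alterations across 3806 cases
l1_shared_cb_pct	metadata	NA	NA	93	0	none	0	share of level 1 alterations that were shared events in cell block pairs; underlying counts not printed	Results: level 1 shared events, 93% for the cell block paired set
l1_shared_scfdna_pct	metadata	NA	NA	83	0	none	0	share of level 1 alterations shared in supernatant cfDNA pairs; underlying counts not printed	Results: level 1 shared events, 83% for the supernatant cfDNA paired set
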