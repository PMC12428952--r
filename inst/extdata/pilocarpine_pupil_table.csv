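arm_id,study,year,drug,concentration_pct,co_drug,dosing,n,baseline_pupil_mm,baseline_sd_mm,post_pupil_mm,post_sd_mm,significant,post_drop_hours_min,post_drop_hours_max,lighting,evidence_level,figure_extracted,arm_type,formulation_group
benozzi_2012,Benozzi,2012,pilocarpine,1.0,diclofenac 0.1%,BID,100,NA,NA,NA,NA,NA,NA,NA,unreported,3,no,active,benozzi
benozzi_2020,Benozzi,2020,pilocarpine,1.0,diclofenac 0.1%,BID,910,NA,NA,NA,NA,NA,NA,NA,unreported,3,no,active,benozzi
benozzi_2021,Benozzi,2021,pilocarpine,1.0,diclofenac 0.1%,BID,148,NA,NA,NA,NA,NA,NA,NA,unreported,3,no,active,benozzi
waring_2022_pilo,Waring,2022,pilocarpine,1.25,NA,QD,163,3.40,NA,1.86,NA,not_tested,1,1,photopic,1,yes,active,1.25% pilocarpine
waring_2022_vehicle,Waring,2022,vehicle,NA,NA,QD,160,3.21,NA,3.09,NA,not_tested,1,1,photopic,1,yes,vehicle,NA
kannarr_2023_pilo,Kannarr,2023,pilocarpine,1.25,NA,BID,114,3.21,NA,1.97,NA,yes,1,1,photopic,1,yes,active,1.25% pilocarpine
kannarr_2023_vehicle,Kannarr,2023,vehicle,NA,NA,BID,116,3.04,NA,3.03,NA,no,1,1,photopic,1,yes,vehicle,NA
lievens_2024_pilo,Lievens,2024,pilocarpine,1.25,NA,QD,39,NA,NA,NA,NA,NA,NA,NA,unreported,1,no,active,1.25% pilocarpine
lievens_2024_vehicle,Lievens,2024,vehicle,NA,NA,QD,41,NA,NA,NA,NA,NA,NA,NA,unreported,1,no,vehicle,NA
mousavi_2024_generic,Mousavi,2024,pilocarpine,1.25,NA,QD,45,2.68,0.81,1.23,0.58,yes,1,2,mesopic,2,no,active,1.25% pilocarpine
mousavi_2024_brand,Mousavi,2024,pilocarpine,1.25,NA,QD,30,2.78,0.43,1.68,0.50,yes,1,2,mesopic,2,no,active,1.25% pilocarpine
waring_2024_pilo,Waring,2024,pilocarpine,1.25,NA,QD,43,NA,NA,NA,NA,NA,NA,NA,unreported,1,no,active,1.25% pilocarpine
waring_2024_placebo,Waring,2024,placebo,NA,NA,QD,43,NA,NA,NA,NA,NA,NA,NA,unreported,1,no,placebo,NA
farid_2024_p02,Farid,2024,pilocarpine,0.2,NA,BID,55,3.17,NA,2.37,NA,yes,1,1,mesopic,1,yes,active,0.2% pilocarpine
farid_2024_p04,Farid,2024,pilocarpine,0.4,NA,BID,55,3.02,NA,2.12,NA,yes,1,1,mesopic,1,yes,active,0.4% pilocarpine
farid_2024_p02_nsaid,Farid,2024,pilocarpine,0.2,diclofenac 0.006%,BID,53,3.28,NA,2.46,NA,yes,1,1,mesopic,1,yes,active,0.2% pilocarpine
farid_2024_p04_nsaid,Farid,2024,pilocarpine,0.4,diclofenac 0.006%,BID,53,3.13,NA,2.22,NA,yes,1,1,mesopic,1,yes,active,0.4% pilocarpine
farid_2024_nsaid_d8,Farid,2024,diclofenac,0.006,NA,BID,58,3.46,NA,3.37,NA,no,1,1,mesopic,1,yes,nsaid_only,NA
farid_2024_nsaid_d15,Farid,2024,diclofenac,0.006,NA,BID,58,3.42,NA,3.30,NA,no,1,1,mesopic,1,yes,nsaid_only,NA
holland_2024_pilo,Holland,2024,pilocarpine,0.4,NA,BID,309,3.36,NA,2.30,0.59,yes,1,1,scotopic,1,no,active,0.4% pilocarpine
holland_2024_vehicle,Holland,2024,vehicle,NA,NA,BID,304,3.51,NA,3.43,0.99,no,1,1,scotopic,1,no,vehicle,NA
vargas_2019,Vargas,2019,pilocarpine,0.247,phenylephrine 0.78% + polyethyleneglycol 0.09% + nepafenac 0.023% + pheniramine 0.034% + naphazoline 0.003%,QD,117,3.30,NA,3.05,NA,yes,2,2,photopic,2,no,active,other pilocarpine
tripathi_2024,Tripathi,2024,pilocarpine,2.0,NA,unreported,120,2.34,0.37,1.57,0.34,yes,0.75,0.75,photopic,2,no,active,other pilocarpine
abdelkader_2015_ge50,Abdelkader,2015,carbachol,2.25,brimonidine 0.2%,QD,30,4.77,NA,2.50,NA,yes,1,1,unreported,1,no,active,carbachol
abdelkader_2015_lt50,Abdelkader,2015,carbachol,2.25,brimonidine 0.2%,QD,30,4.72,NA,2.61,NA,yes,1,1,unreported,1,no,active,carbachol
abdelkader_2015_placebo_ge50,Abdelkader,2015,placebo,NA,NA,QD,18,4.57,NA,4.48,NA,no,1,1,unreported,1,no,placebo,NA
abdelkader_2015_placebo_lt50,Abdelkader,2015,placebo,NA,NA,QD,18,4.80,NA,4.78,NA,no,1,1,unreported,1,no,placebo,NA
abdelkader_2016_carb_brim,Abdelkader,2016,carbachol,3.0,brimonidine 0.2%,QD,10,4.30,0.50,1.20,0.30,yes,1,1,unreported,1,no,active,carbachol
abdelkader_2016_carb_then_brim,Abdelkader,2016,carbachol,3.0,brimonidine 0.2% (sequential),QD,10,4.30,0.50,1.90,0.30,yes,1,1,unreported,1,no,active,carbachol
abdelkader_2016_carb,Abdelkader,2016,carbachol,3.0,NA,QD,10,4.30,0.50,2.80,0.50,yes,1,1,unreported,1,no,active,carbachol
abdelkader_2016_brim,Abdelkader,2016,brimonidine,0.2,NA,QD,10,4.30,0.50,3.95,0.50,no,1,1,unreported,1,no,comparator,NA
pepose_2021_phento,Pepose,2021,phentolamine mesylate,1.0,NA,QD,19,4.69,0.95,3.71,0.81,yes,10,12,photopic,1,no,active,phentolamine
pepose_2021_vehicle,Pepose,2021,vehicle,NA,NA,QD,20,NA,NA,NA,NA,NA,10,12,photopic,1,no,vehicle,NA
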