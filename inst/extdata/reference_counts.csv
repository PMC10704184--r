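variable,category,count
age_group,"[0, 18)",74
age_group,"[18, 30)",393
age_group,"[30, 40)",529
age_group,"[40, 50)",687
age_group,"[50, 65)",1434
age_group,"[65, 75)",909
age_group,"[75, 85)",597
age_group,"[85, 140)",284
age_group,Not reported,93
race,American Indian or Alaska Native,17
race,Asian,294
race,Black or African American,1386
race,Native Hawaiian or other Pacific Islander,15
race,White,2568
race,Not reported,554
race,Other,166
sex_at_birth,Female,2533
sex_at_birth,Male,2464
sex_at_birth,Other,0
sex_at_birth,Not reported,3
ethnicity,Hispanic or Latino,499
ethnicity,Not Hispanic or Latino,4443
ethnicity,Not reported,58
covid_status,No,2602
covid_status,Not reported,1
covid_status,Yes,2397
modality,CR,2049
modality,CT,910
modality,DX,2596
modality,MR,27
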