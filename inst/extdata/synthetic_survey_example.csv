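study_id,species,mean,sd,se,n,range_low,range_high,iqr_low,iqr_high,period_h,rate_basis,brood_size,uses
s01,Parus major,14.2,6.9,,28,,,,,1,count,,2
s02,Passer domesticus,6.1,,0.55,40,,,,,1,count,,1
s03,Ficedula hypoleuca,8.5,,,30,1,24,,,1,count,,1
s04,Sturnus vulgaris,4.8,2.1,,22,,,,,0.5,per-hour,,1
s05,Taeniopygia guttata,3.1,,,25,,,,,1,per-hour-per-chick,3.8,1
s06,Melanerpes formicivorus,3.9,1.8,,18,,,,,1,count,,3
s07,Agelaius phoeniceus,22.7,9.4,,35,,,,,2,per-hour,,1
s08,Pomatostomus ruficeps,11.3,,,26,,,2.5,16.0,1,count,,1
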