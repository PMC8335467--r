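panel,row,reference,igrt,art1,art2,art3,sd_reference,sd_igrt,sd_art1,sd_art2,sd_art3
per_criterion,V36.25Gy_PTV,47,544,93,66,262,,,,,
per_criterion,D98pct_PTV,9,852,88,69,16,,,,,
per_criterion,V37Gy_bladder,0,1800,292,333,92,,,,,
per_criterion,V36Gy_rectum,0,5943,1424,1754,254,,,,,
total,total,56,9139,1897,2222,624,,,,,
per_patient,P1,2.0,14.2,1.0,0.3,1.6,,10.6,0.5,0.4,0.9
per_patient,P2,3.0,35.0,3.4,1.3,2.3,,36.5,0.7,0.4,1.0
per_patient,P3,1.6,67.7,0.1,5.9,1.2,,54.9,0.2,9.7,0.8
per_patient,P4,2.3,77.3,27.7,33.7,21.0,,51.0,22.7,25.7,28.7
per_patient,P5,1.0,24.9,8.2,5.0,0.5,,25.2,15.7,9.8,0.6
per_patient,P6,1.5,84.5,22.5,17.8,2.9,,104.9,33.6,33.5,2.7
per_patient,P7,4.1,82.5,15.8,19.5,9.3,,51.5,20.3,25,14.0
per_patient,P8,1.0,80.5,17.7,20.4,1.7,,64.4,25.2,21.4,1.6
per_patient,P9,1.8,9.9,0.1,0,1.4,,10.1,0.2,0.1,0.1
per_patient,P10,10.2,94.5,20.8,18.7,4.8,,85.3,13.8,8.5,0.7
per_patient,P11,1.2,18.9,0.1,0.1,0.7,,20.1,0.1,0.2,0.6
per_patient,P12,1.9,34.3,1.5,0.3,2.0,,23.7,1.9,0.6,0.5
per_patient,P13,0,25.8,0.9,0,1.4,,20.0,1.8,0,1.1
per_patient,P14,0.8,157.6,39.8,40.9,19.9,,218.6,75.4,77.8,29.5
per_patient,P15,2.0,58.4,13.6,17.7,2.7,,55.9,21.9,21.8,1.1
per_patient,P16,0,4.8,0,0,0,,4.4,0.1,0,0.1
per_patient,P17,1.2,38.3,3.3,8.5,2.4,,32.2,6.3,10.1,0.7
per_patient,P18,0.4,17.0,0.8,0.8,1.1,,14.5,1.0,1.0,0.7
per_patient,P19,2.5,58.3,5.7,6.1,1.8,,63.5,5.5,6.7,1.3
per_patient,P20,2.2,56.2,7.1,8.3,1.9,,24.0,5.8,5.6,0.7
per_patient,P21,0,7.3,0.6,0.3,0,,13.5,0.6,0.7,0
per_patient,P22,1.1,70.6,24.7,19.1,6.6,,21.4,15.3,14.0,8.7
per_patient,P23,2.2,46.0,24.5,17.0,1.8,,47.2,32.4,22.0,0.6
per_patient,P24,0,288.7,53.8,81.2,24.6,,115.4,51.1,76.3,35.2
per_patient,P25,5.0,57.7,10.0,18.2,4.1,,51.8,9.2,18.2,0.6
per_patient,P26,4.2,15.5,2.3,1.2,1.8,,14.9,1.6,1.7,1.0
per_patient,P27,0,71.5,29.5,41.1,3.2,,44.4,23.6,31.2,3.7
per_patient,P28,1.0,12.7,0.6,0.7,0.4,,25.4,0.5,1.1,0.4
per_patient,P29,0.5,210.2,43.1,59.9,1.2,,108.7,21.9,29.7,1.3
per_patient,P30,0.0,2.1,0,0,0,,3.1,0,0,0
per_patient,P31,1.2,0.9,0,0.1,0.4,,0.6,0,0.3,0.4
per_patient,P32,0.0,3.9,0.1,0.2,0,,7.7,0.1,0.4,0
cohort_mean,mean,1.7,57.1,11.9,13.9,3.9,2.0,87.4,25.7,30.6,11.8
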