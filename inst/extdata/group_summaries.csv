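comparison,m1,sem1,n1,m2,sem2,n2,t_printed,df
pct_drd2_pet1_control_vs_cko,15.23,2.41,6,3.87,0.73,6,4.514,10
gad2_puncta_male_vs_female,20.46,2.243,5,12.20,2.427,5,2.498,8
pct_gad2_male_vs_female,86.47,4.181,5,74.00,5.168,5,1.876,8
pct_drd2_e78_control_vs_cko,35.97,2.403,6,36.53,3.621,6,0.1291,10
cko_pct_gad2_male_vs_female,87.44,3.034,6,75.76,0.5862,4,3.057,8
cko_gad2_puncta_male_vs_female,14.25,1.325,6,10.13,2.074,4,1.768,8
nucleus_area_male_vs_female,114.9,3.030,6,110.9,1.768,4,0.9931,8
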