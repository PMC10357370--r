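factor,level,comorbid,noncomorbid
gender,boy,3203,8375
gender,girl,4033,7257
siblings,yes,2011,4549
siblings,no,5225,11083
region_level,first_line,3816,7650
region_level,second_line,3420,7982
edu_status,junior,3323,8517
edu_status,senior,3913,7115
father_edu,primary_or_below,1009,1881
father_edu,junior_high,2751,5982
father_edu,senior_high_or_above,3476,7769
mother_edu,primary_or_below,1520,2811
mother_edu,junior_high,2633,5717
mother_edu,senior_high_or_above,3083,7104
family_income,low,1209,1562
family_income,medium,5058,11598
family_income,high,969,2472
num_friends,le2,5512,10527
num_friends,ge3,1724,5105
learning_burden,low,367,1114
learning_burden,medium,3377,10317
learning_burden,high,3492,4201
family_psychosis,yes,570,797
family_psychosis,no,6666,14835
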