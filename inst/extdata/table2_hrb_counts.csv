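factor,level,comorbid,noncomorbid
diet,low,1519,4563
diet,medium,2294,5148
diet,high,3423,5921
smoking,low,6972,15364
smoking,medium,145,132
smoking,high,119,136
physical_inactivity,low,837,2336
physical_inactivity,medium,1479,3631
physical_inactivity,high,4920,9665
sleep,low,1793,5679
sleep,medium,2728,6056
sleep,high,2715,3897
hrb_index,low,294,1507
hrb_index,medium,2167,6213
hrb_index,high,4775,7912
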