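#schema=melscreen-lifetable-1
age_low,age_high,sex,rate
15,20,male,5e-04
20,25,male,8e-04
25,30,male,9e-04
30,35,male,0.001
35,40,male,0.0013
40,45,male,0.0018
45,50,male,0.0025
50,55,male,0.004
55,60,male,0.006
60,65,male,0.009
65,70,male,0.014
70,75,male,0.022
75,80,male,0.036
80,85,male,0.06
15,20,female,3e-04
20,25,female,4e-04
25,30,female,5e-04
30,35,female,6e-04
35,40,female,9e-04
40,45,female,0.0013
45,50,female,0.0019
50,55,female,0.003
55,60,female,0.0045
60,65,female,0.007
65,70,female,0.011
70,75,female,0.017
75,80,female,0.028
80,85,female,0.048
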