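variable,level,once_or_less,one_to_three,three_or_more
sex,female,91,428,487
sex,male,54,360,326
age,<70,101,492,472
age,70-74,33,174,178
age,>74,11,122,163
education,elementary,104,518,568
education,high_school,18,134,126
education,superior,23,136,119
bmi,normal,60,291,313
bmi,overweight,54,333,334
bmi,obese,30,154,158
smoking,never,61,310,359
smoking,former,57,362,336
smoking,current,27,113,116
diabetes,yes,19,80,107
diabetes,no,126,708,706
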