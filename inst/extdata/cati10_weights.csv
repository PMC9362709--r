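component,weight
food_secure,0.199
attended_preschool,0.025
grad_hs_on_time,0.285
math_proficient,0.052
reading_proficient,0.054
non_low_birthweight,0.052
non_obese,0.020
not_fair_poor_health,0.027
didnt_smoke,0.192
didnt_try_marijuana,0.069
never_arrested,0.027
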