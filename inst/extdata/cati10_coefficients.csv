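component,fl,pd,wr,sa,ls
food_secure,0.168,-0.166,-0.228,-0.177,0.171
attended_preschool,0,-0.102,0,0,0
grad_hs_on_time,0.274,-0.224,-0.357,-0.171,0.273
math_proficient,0,0,-0.121,-0.118,0
reading_proficient,0.163,-0.067,0,0,0
non_low_birthweight,0.123,0,-0.096,0,0
non_obese,0,0,-0.084,0,0
not_fair_poor_health,0,0,0,-0.136,0
didnt_smoke,0.236,-0.224,-0.267,0,0.104
didnt_try_marijuana,0,-0.130,0,0,0.192
never_arrested,0,0,0,0,0.141
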