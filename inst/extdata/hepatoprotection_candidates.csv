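name,n_active_ingredients,matched_rules,assessable,screened
Qian Hu,25,,TRUE,FALSE
Ling Xiao Hua,22,1,TRUE,TRUE
Fu Pen Zi,21,1|2|5,TRUE,TRUE
Gui Zhi,21,4,TRUE,FALSE
E Bu Shi Cao,20,,TRUE,FALSE
Fang Feng,20,4,TRUE,FALSE
Gao Ben,20,,TRUE,TRUE
Jing Jie,20,,TRUE,FALSE
Xiang Ru,20,,TRUE,FALSE
Qiang Huo,19,,TRUE,FALSE
Gao Liang Jiang,18,,TRUE,TRUE
Mai Ya,17,3,TRUE,TRUE
Man Shan Hong,17,,TRUE,FALSE
Qing Guo,17,1|3,TRUE,TRUE
Tian Shan Xue Lian,17,,FALSE,FALSE
Che Qian Zi,16,2|5,TRUE,TRUE
Hua Ju Hong,16,,TRUE,FALSE
Lian Qian Cao,16,,TRUE,FALSE
Bai Lian,15,,TRUE,FALSE
Gou Gu Ye,15,,TRUE,TRUE
Gu Sui Bu,15,,TRUE,TRUE
Hu Lu Ba,15,,TRUE,TRUE
La Jiao,15,,TRUE,TRUE
Wei Ling Cai,15,,TRUE,FALSE
Xi He Liu,15,3,TRUE,FALSE
Zhi Shi,15,1,TRUE,TRUE
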