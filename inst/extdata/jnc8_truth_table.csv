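race,ckd,class_label,permitted,rule_fired
White,FALSE,ACEi,TRUE,general
White,FALSE,ARB,TRUE,general
White,FALSE,thiazide,TRUE,general
White,FALSE,CCB,TRUE,general
White,FALSE,beta_blocker,FALSE,general
White,FALSE,other,FALSE,general
White,FALSE,ACEi-thiazide,TRUE,general
White,FALSE,ACEi-CCB,TRUE,general
White,FALSE,ARB-thiazide,TRUE,general
White,FALSE,CCB-thiazide,TRUE,general
White,FALSE,beta_blocker-thiazide,FALSE,general
White,TRUE,ACEi,TRUE,ckd
White,TRUE,ARB,TRUE,ckd
White,TRUE,thiazide,FALSE,ckd
White,TRUE,CCB,FALSE,ckd
White,TRUE,beta_blocker,FALSE,ckd
White,TRUE,other,FALSE,ckd
White,TRUE,ACEi-thiazide,TRUE,ckd
White,TRUE,ACEi-CCB,TRUE,ckd
White,TRUE,ARB-thiazide,TRUE,ckd
White,TRUE,CCB-thiazide,FALSE,ckd
White,TRUE,beta_blocker-thiazide,FALSE,ckd
Black,FALSE,ACEi,FALSE,black
Black,FALSE,ARB,FALSE,black
Black,FALSE,thiazide,TRUE,black
Black,FALSE,CCB,TRUE,black
Black,FALSE,beta_blocker,FALSE,black
Black,FALSE,other,FALSE,black
Black,FALSE,ACEi-thiazide,FALSE,black
Black,FALSE,ACEi-CCB,FALSE,black
Black,FALSE,ARB-thiazide,FALSE,black
Black,FALSE,CCB-thiazide,TRUE,black
Black,FALSE,beta_blocker-thiazide,FALSE,black
Black,TRUE,ACEi,TRUE,ckd
Black,TRUE,ARB,TRUE,ckd
Black,TRUE,thiazide,FALSE,ckd
Black,TRUE,CCB,FALSE,ckd
Black,TRUE,beta_blocker,FALSE,ckd
Black,TRUE,other,FALSE,ckd
Black,TRUE,ACEi-thiazide,TRUE,ckd
Black,TRUE,ACEi-CCB,TRUE,ckd
Black,TRUE,ARB-thiazide,TRUE,ckd
Black,TRUE,CCB-thiazide,FALSE,ckd
Black,TRUE,beta_blocker-thiazide,FALSE,ckd
Other,FALSE,ACEi,TRUE,general
Other,FALSE,ARB,TRUE,general
Other,FALSE,thiazide,TRUE,general
Other,FALSE,CCB,TRUE,general
Other,FALSE,beta_blocker,FALSE,general
Other,FALSE,other,FALSE,general
Other,FALSE,ACEi-thiazide,TRUE,general
Other,FALSE,ACEi-CCB,TRUE,general
Other,FALSE,ARB-thiazide,TRUE,general
Other,FALSE,CCB-thiazide,TRUE,general
Other,FALSE,beta_blocker-thiazide,FALSE,general
Other,TRUE,ACEi,TRUE,ckd
Other,TRUE,ARB,TRUE,ckd
Other,TRUE,thiazide,FALSE,ckd
Other,TRUE,CCB,FALSE,ckd
Other,TRUE,beta_blocker,FALSE,ckd
Other,TRUE,other,FALSE,ckd
Other,TRUE,ACEi-thiazide,TRUE,ckd
Other,TRUE,ACEi-CCB,TRUE,ckd
Other,TRUE,ARB-thiazide,TRUE,ckd
Other,TRUE,CCB-thiazide,FALSE,ckd
Other,TRUE,beta_blocker-thiazide,FALSE,ckd
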