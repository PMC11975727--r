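code,product_name,ingredient,drug_class,unit_mg
104375,lisinopril 10 mg tablet,lisinopril,ACEi,10
104376,lisinopril 20 mg tablet,lisinopril,ACEi,20
104490,enalapril 5 mg tablet,enalapril,ACEi,5
104491,enalapril 10 mg tablet,enalapril,ACEi,10
203160,losartan 50 mg tablet,losartan,ARB,50
203161,losartan 100 mg tablet,losartan,ARB,100
203320,valsartan 80 mg tablet,valsartan,ARB,80
203321,valsartan 160 mg tablet,valsartan,ARB,160
310798,hydrochlorothiazide 12.5 mg tablet,hydrochlorothiazide,thiazide,12.5
310799,hydrochlorothiazide 25 mg tablet,hydrochlorothiazide,thiazide,25
310950,chlorthalidone 25 mg tablet,chlorthalidone,thiazide,25
310951,chlorthalidone 50 mg tablet,chlorthalidone,thiazide,50
402695,amlodipine 5 mg tablet,amlodipine,CCB,5
402696,amlodipine 10 mg tablet,amlodipine,CCB,10
402830,diltiazem 120 mg capsule,diltiazem,CCB,120
402831,diltiazem 240 mg capsule,diltiazem,CCB,240
508033,metoprolol 50 mg tablet,metoprolol,beta_blocker,50
508034,metoprolol 100 mg tablet,metoprolol,beta_blocker,100
508210,atenolol 25 mg tablet,atenolol,beta_blocker,25
508211,atenolol 50 mg tablet,atenolol,beta_blocker,50
609552,clonidine 0.1 mg tablet,clonidine,other,0.1
609553,clonidine 0.2 mg tablet,clonidine,other,0.2
609710,hydralazine 50 mg tablet,hydralazine,other,50
609711,hydralazine 100 mg tablet,hydralazine,other,100
705120,lisinopril-hydrochlorothiazide 10-12.5 mg tablet,lisinopril,ACEi,10
705120,lisinopril-hydrochlorothiazide 10-12.5 mg tablet,hydrochlorothiazide,thiazide,12.5
705121,lisinopril-hydrochlorothiazide 20-25 mg tablet,lisinopril,ACEi,20
705121,lisinopril-hydrochlorothiazide 20-25 mg tablet,hydrochlorothiazide,thiazide,25
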