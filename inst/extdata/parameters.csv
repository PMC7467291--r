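name,base,family,se,low,high,events,denom,range_type,units,source
prevalence,0.095,beta,,,,7,74,counts,proportion,Tanner intermediate-risk surveillance arm (7/74)
stage_local,0.875,derived,,,,,,none,proportion,1 - stage_regional
stage_regional,0.125,beta,,0.078,0.165,,,range,proportion,initial regional share of malignant nodules
growth_first_month,0.28,beta,,0.13,0.29,,,range,probability/month,benign nodule growth detected during first month
growth_subsequent,0.005,beta,,0,0.01,,,range,probability/month,benign nodule growth per subsequent month
mort_undiag_malig,0.02688,beta,,,,,,pm50,probability/month,life expectancy 36.7 months for untreated 2cm nodule
mort_distant_y1,0.1255,beta,,,,,,pm50,probability/month,distant cancer mortality months 0-12
mort_distant_y2,0.0670,beta,,,,,,pm50,probability/month,distant cancer mortality months 13-24
mort_distant_y3,0.0589,beta,,,,,,pm50,probability/month,distant cancer mortality months 25-36
mort_distant_y4,0.0150,beta,,,,,,pm50,probability/month,distant cancer mortality months 37-48
mort_local_y1,0.0106,beta,,,,,,pm50,probability/month,recurrence mortality (treated local) months 0-12
mort_local_y2,0.0100,beta,,,,,,pm50,probability/month,recurrence mortality (treated local) months 13-24
mort_local_y3,0.0090,beta,,,,,,pm50,probability/month,recurrence mortality (treated local) months 25-36
mort_local_y4,0.0114,beta,,,,,,pm50,probability/month,recurrence mortality (treated local) months 37-48
mort_regional_y1,0.0340,beta,,,,,,pm50,probability/month,regional cancer mortality months 0-12
mort_regional_y2,0.0296,beta,,,,,,pm50,probability/month,regional cancer mortality months 13-24
mort_regional_y3,0.0225,beta,,,,,,pm50,probability/month,regional cancer mortality months 25-36
mort_regional_y4,0.0155,beta,,,,,,pm50,probability/month,regional cancer mortality months 37-48
prob_progression,0.19224,beta,,0.18887,0.21005,,,range,probability/month,undiagnosed local->regional and regional->distant (95% CI)
mort_biopsy,0.000907384,beta,,,,29,31960,counts,probability/event,mortality due to guided needle biopsy (29/31960)
biopsy_complication,0.00719650,beta,,,,230,31960,counts,probability/event,serious adverse event from guided needle biopsy (230/31960)
mort_surgery_malig,0.042,beta,,0.017,0.053,,,range,probability/event,surgery-related mortality for malignant nodule
mort_surgery_benign,0.005,beta,,0.002,0.016,,,range,probability/event,surgery-related mortality for benign nodule
comp_surgery_malig,0.084,beta,,0.048,0.11,,,range,probability/event,surgery complications for malignant nodules
comp_surgery_benign,0.065,beta,,0.033,0.13,,,range,probability/event,surgery complications for benign nodules
prop_radiotherapy,0.142857,beta,,,,5,35,counts,proportion,patients receiving radiotherapy with surgery (5/35)
prop_chemotherapy,0.314286,beta,,,,11,35,counts,proportion,patients receiving chemotherapy with surgery (11/35)
cost_aabt,70,fixed,,,,,,none,GBP,AABT list price (Oncimmune)
cost_ct,85.56,fixed,,,,,,none,GBP,CT scan single area no contrast (RD20A)
cost_mdt,111.99,fixed,,,,,,none,GBP,multidisciplinary team review (CMDT_Oth)
cost_needle_biopsy,948.92,fixed,,,,,,none,GBP,guided needle biopsy (DZ71Z)
cost_surgery_nocomp,7713.03,fixed,,,,,,none,GBP,surgery without complications (DZ02K)
cost_surgery_comp,10177.74,fixed,,,,,,none,GBP,surgery with complications (DZ02H)
cost_surgical_biopsy_nocomp,3091.08,fixed,,,,,,none,GBP,surgical biopsy without complications (DZ63C)
cost_surgical_biopsy_comp,6733.76,fixed,,,,,,none,GBP,surgical biopsy with complications (DZ63A)
cost_radiotherapy,3252,fixed,,,,,,none,GBP,radiotherapy course (2016/17 prices)
cost_chemotherapy,4155.15,fixed,,,,,,none,GBP,chemotherapy course (2016/17 prices)
u_age_55_64,0.810,beta,0.05,,,,,none,utility,EQ-5D UK population norm age 55-64
u_age_65_74,0.773,beta,0.05,,,,,none,utility,EQ-5D UK population norm age 65-74
u_age_75plus,0.703,beta,0.05,,,,,none,utility,EQ-5D UK population norm age 75+
u_local,0.71,beta,0.05,,,,,none,utility,local-stage cancer utility at 12 months (n=33)
u_regional,0.65,beta,0.05,,,,,none,utility,regional-stage cancer utility at 12 months (n=12)
u_distant,0.62,beta,0.05,,,,,none,utility,distant-stage cancer utility at 12 months (n=4)
u_biopsy_sae_decrement,0.2,fixed,,,,,,none,utility,utility decrement for serious biopsy adverse event (applied for one cycle)
hsroc_lambda,3.156,normal,0.2296,,,,,none,logit,HSROC accuracy parameter Lambda (metandi re-analysis of 12 CT studies)
hsroc_beta,-0.5362433,fixed,,,,,,none,logit,HSROC shape parameter beta (held constant)
ct_spec,0.7234,beta,0.0276,,,,,none,proportion,CT specificity (metandi summary)
ct_sens,0.923,derived,,,,,,none,proportion,CT sensitivity via HSROC curve at summary specificity
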