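id,group,base_value,unit,family,dist_params,source
p_tox_grade1,transition,5.088,%,degenerate,,IMRT/IGRT late-toxicity cohort (V15_SB < 150 ml)
p_tox_grade2,transition,1.594,%,degenerate,,IMRT/IGRT late-toxicity cohort (V15_SB < 150 ml)
p_tox_grade3,transition,0.658,%,degenerate,,IMRT/IGRT late-toxicity cohort (V15_SB < 150 ml)
p_tox_grade4,transition,0.216,%,degenerate,,IMRT/IGRT late-toxicity cohort (V15_SB < 150 ml)
ntcp_imrt_igrt,transition,0.180,fraction,beta,,small-bowel NTCP model
ntcp_imrt,transition,0.265,fraction,beta,,small-bowel NTCP model
ntcp_3dcrt,transition,0.395,fraction,beta,,small-bowel NTCP model
p_loperamide_success,treatment,92.80,%,beta,alpha=41.00;beta=22.00,antidiarrheal management study
p_second_line_ab,treatment,44.44,%,beta,alpha=32.00;beta=40.00,second-line management audit
p_second_line_bas,treatment,55.56,%,beta,alpha=40.00;beta=32.00,second-line management audit
p_ab_success,treatment,41.85,%,beta,alpha=15.00;beta=17.00,second-line management audit
p_bas_success,treatment,30.87,%,beta,alpha=14.00;beta=26.00,second-line management audit
p_surgery,treatment,22.80,%,beta,alpha=61.00;beta=90.00,small-bowel obstruction cohort
p_supportive,treatment,77.20,%,beta,alpha=90.00;beta=61.00,small-bowel obstruction cohort
p_surgery_survival,treatment,96.22,%,beta,alpha=32.64;beta=15.36,surgical outcome series
p_surgery_death,treatment,3.783,%,beta,alpha=32.64;beta=15.36,surgical outcome series
p_supportive_survival,treatment,99.16,%,beta,alpha=167775;beta=2845,non-operative outcome series
p_supportive_death,treatment,0.837,%,beta,alpha=2845;beta=167775,non-operative outcome series
p_rec1_surgery,recurrence,1.181,%,beta,alpha=8.277;beta=65.62,adhesive obstruction follow-up
p_rec1_supportive,recurrence,2.106,%,beta,alpha=42.61;beta=179.7,adhesive obstruction follow-up
p_rec2_surgery,recurrence,2.124,%,beta,alpha=1.174;beta=4.904,adhesive obstruction follow-up
p_rec2_supportive,recurrence,4.852,%,beta,alpha=63.86;beta=99.09,adhesive obstruction follow-up
p_rec3_surgery,recurrence,1.965,%,beta,alpha=0.062;beta=0.283,adhesive obstruction follow-up
p_rec3_supportive,recurrence,6.332,%,beta,alpha=41.77;beta=45.23,adhesive obstruction follow-up
p_rec4_surgery,recurrence,3.678,%,beta,alpha=63.86;beta=99.09,adhesive obstruction follow-up
p_rec4_supportive,recurrence,7.726,%,beta,alpha=0.057;beta=0.124,adhesive obstruction follow-up
cost_loperamide_unit,direct_cost,0.043,EUR,gamma,shape=100.0;scale=4.312e-4,national formulary
cost_ab_unit,direct_cost,0.011,EUR,gamma,shape=100.0;scale=12.70e-4,national formulary
cost_bas_unit,direct_cost,0.127,EUR,gamma,shape=100.0;scale=1.082e-4,national formulary
cost_hosp_surgery,direct_cost,11495.840,EUR,gamma,shape=100.0;scale=115.0,inpatient care tariffs
cost_hosp_supportive,direct_cost,4760.970,EUR,gamma,shape=100.0;scale=47.61,inpatient care tariffs
activity_rate,indirect_cost,75.10,%,beta,alpha=75.10;beta=24.90,labour-market statistics
wage_daily,indirect_cost,250.118,EUR,gamma,shape=100.0;scale=2.501,wage statistics
wage_annual,indirect_cost,55025.900,EUR,gamma,shape=100.0;scale=550.3,wage statistics
sickdays_event,indirect_cost,14.550,days,lognormal,meanlog=2.678,sick-leave study (IBD)
sickdays_management,indirect_cost,9.650,days,lognormal,meanlog=2.677,sick-leave study (IBD)
sickleave_hosp_factor,indirect_cost,0.500,factor,lognormal,meanlog=-0.693,expert opinion
disutility_pharma,utility,-24.7,%,degenerate,,Crohn's disease utility proxy
disutility_supportive,utility,-32.3,%,degenerate,,Crohn's disease utility proxy
disutility_surgery,utility,-38.7,%,degenerate,,Crohn's disease utility proxy
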