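id,role,arm,baseline,low,high,distribution,note
p_nocav_cavity,probability,standard,0.06873,0.0665,0.071,beta,6-month progression no-cavity to cavity; national survey SB Brasil 2010
q_gic,probability,both,0.873,0.869,0.877,beta,cavity treated with glass ionomer cement; SB Brasil 2010 treatment-need codes
q_hall,probability,both,0.004,0.003,0.005,beta,cavity treated with Hall technique crown; SB Brasil 2010 treatment-need codes
s_gic,probability,standard,0.63,0.49,0.74,beta,glass ionomer success per 6-month cycle; RCT additional file
s_hall,probability,standard,0.98,0.88,0.99,beta,Hall technique success per 6-month cycle; RCT additional file
p_prev_cavity,probability,standard,0.28,0.14,0.58,beta,previous-cavity to cavity per 6-month cycle
p_nocav_cavity_fv,probability,fv,0.0604824,0.0586,0.0625,beta,derived product 0.06873 x 0.88; printed DSA bounds
f_gic_fv,probability,fv,0.3256,0.2288,0.4488,beta,derived product 0.37 x 0.88; printed DSA bounds
f_hall_fv,probability,fv,0.0176,0.0088,0.1056,beta,derived product 0.02 x 0.88; printed DSA bounds
p_prev_cavity_fv,probability,fv,0.2464,0.1232,0.5104,beta,derived product 0.28 x 0.88; printed DSA bounds
eff_rr,relative-risk,both,0.88,0.81,0.95,lognormal,fluoride varnish relative risk from systematic review meta-analysis
c_routine,cost,both,118.50,94.8,142.2,gamma,routine visit cost per cycle for every health state; 2022 Reais
c_gic,cost,both,179.50,143.6,215.4,gamma,glass ionomer restoration cost; 2022 Reais
c_hall,cost,both,254.50,203.6,305.4,gamma,Hall technique restoration cost; 2022 Reais
c_ext,cost,both,172.50,138,207,gamma,tooth extraction cost; 2022 Reais
c_fv,cost,fv,78.00,62.4,93.6,gamma,fluoride varnish application both arches per cycle; 2022 Reais
daly_weight,disability-weight,both,0.01,0.01,0.01,fixed,annual disability weight while a cavitated lesion is present; GBD 2019
discount_rate_annual,rate,both,0.05,0.05,0.05,fixed,annual discount rate applied to costs and outcomes
n_cycles,count,both,8,8,8,fixed,number of 6-month cycles (4-year horizon)
cycle_length_years,rate,both,0.5,0.5,0.5,fixed,cycle length in years
wtp_daly,cost,both,40000,40000,40000,fixed,willingness to pay per DALY avoided (approx 1 GDP per capita)
wtp_cavity,cost,both,60,60,60,fixed,willingness to pay per cavity avoided from a Brazilian study
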