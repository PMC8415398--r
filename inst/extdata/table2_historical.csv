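year,series,actual,simulated,orientation
2012,insured_employees,182.15,180.7244,sim_minus_actual
2013,insured_employees,192.26,191.4216,sim_minus_actual
2014,insured_employees,203.64,199.4962,sim_minus_actual
2015,insured_employees,212.23,209.7704,sim_minus_actual
2016,insured_employees,223.16,228.185,sim_minus_actual
2017,insured_employees,242.75,241.956,sim_minus_actual
2018,insured_employees,257.4,257.4472,sim_minus_actual
2012,disposable_income,37576,38382.08,actual_minus_sim
2013,disposable_income,41360,36772,actual_minus_sim
2014,disposable_income,39625,39539.296,actual_minus_sim
2015,disposable_income,42607,42923.712,actual_minus_sim
2016,disposable_income,46254,46417.632,actual_minus_sim
2017,disposable_income,50019,50484.128,actual_minus_sim
2018,disposable_income,54401,51847.36,actual_minus_sim
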