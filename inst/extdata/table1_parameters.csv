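parameter,value,unit,source
insured_urban_employees,273.88,10000_persons,yearbook_2020
per_capita_gdp,142739,yuan,yearbook_2020
per_capita_disposable_income,55870,yuan,yearbook_2020
insured_urban_rural_residents,148,10000_persons,yearbook_2020
cost_institutional_care,30000,yuan_per_person_year,survey
cost_home_care,18000,yuan_per_person_year,survey
growth_insured_urban_employees,6,percent_per_year,yearbook_2011_2020
growth_insured_urban_rural_residents,5.9,percent_per_year,yearbook_2011_2020
growth_per_capita_gdp,5,percent_per_year,yearbook_2000_2020
government_subsidy_rate,0.04,percent_of_gdp,assumed
growth_per_capita_disposable_income,8,percent_per_year,yearbook_2015_2020
enterprise_contribution_rate,0.04,percent_of_gdp,assumed
individual_payment_rate,0.06,percent_of_income,assumed
severe_disability_rate,0.3,percent_of_insured,literature_survey
share_institutional_care,3,percent,literature
share_home_care,97,percent,literature
reimbursement_ratio,70,percent,assumed
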