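country: Benin
base_year: 2010.0
end_year: 2050.0
policy:
  expected_school_years_f: 9.42
  expected_school_years_m: 12.68
  mean_school_years_f: 2.06
  mean_school_years_m: 4.55
  mean_school_years_both: 3.31
  cpr_modern: 7.9
  cpr_traditional: 5.0
  postpartum_insusceptibility: 12.300000000000001
  sterility_45_49: 4.100000000000001
  gci_public_institutions: 2.95
  gci_labor_flexibility: 3.39
  gci_financial_efficiency: 2.96
  gci_ict_use: 3.2
  imports_pct_gdp: 38.100000000000001
demography:
  tfr: 4.9
  pct_married: 70.399999999999991
  pct_births_at_risk: 52.300000000000004
  imr: 46.0
  u5mr: 75.0
  mmr: 340.0
  eff_modern: 0.95
  eff_traditional: 0.5
  e0_female: 59.600000000000001
  e0_gap_female_minus_male: 2.74
economy:
  gdp_pc: 605.0
  gdp_growth: 0.037
  capital_formation_pc: 141.0
  capital_stock_growth: 0.005
  depreciation: 0.04
  initial_employment_15plus: 4133182.0
  employment_growth: 0.034
  labor_force_participation: 1.0
  primary_edu_cost_pct_gdp_pc: 15.02
  capital_stock_per_15plus: 11190.0
pyramid:
  age_start:
  - 0
  - 5
  - 10
  - 15
  - 20
  - 25
  - 30
  - 35
  - 40
  - 45
  - 50
  - 55
  - 60
  - 65
  - 70
  - 75
  - 80
  female:
  - 808313.60702188720461
  - 683756.087946175481193
  - 578426.447966854670085
  - 443091.730988643190358
  - 374880.650464260252193
  - 317189.824679919634946
  - 268393.960270024021156
  - 227119.245764465042157
  - 192204.384738404041855
  - 162667.674693662760546
  - 137679.192543877579737
  - 116537.293620041382383
  - 98648.754422454003361
  - 42087.239233522908762
  - 35631.882627116145159
  - 30168.847408348356112
  - 25545.289747791943228
  male:
  - 848729.287372981314547
  - 707260.203469325206243
  - 589271.94386623299215
  - 444476.392647982633207
  - 370194.642333457013592
  - 308268.860860796878114
  - 256651.724508210434578
  - 213634.040547199925641
  - 177789.055883023742354
  - 147925.916674549604068
  - 123050.778336090588709
  - 102334.310960098853684
  - 85084.550689366573351
  - 35642.630725889714085
  - 29619.002433790294162
  - 24606.466167434129602
  - 20436.23179823355531
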