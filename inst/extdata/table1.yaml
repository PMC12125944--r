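# Base-case inputs: monthly event probabilities, state utilities,
# hospital costs and provider fees (2023 CAD), and fixed model constants.
# SDs follow the sources; plausible ranges are the published ones where a
# non-degenerate range was printed (utility ranges of 0-1 are left to the
# loader's central-95%-interval default).
probabilities:
  p_fail_TKA:    {mean: 29.559e-4, sd: 5.9118e-4, low: 23.946e-4, high: 36.587e-4}
  p_fail_UKA:    {mean: 8.1627e-4, sd: 1.63254e-4, low: 7.433e-4, high: 8.897e-4}
  p_fail_HTO:    {mean: 33.158e-4, sd: 6.6316e-4, low: 32.449e-4, high: 46.393e-4}
  f_instab_TKA:  {mean: 0.124, sd: 0.0248, low: 0.099, high: 0.149}
  f_instab_UKA:  {mean: 0.062, sd: 0.0124, low: 0.049, high: 0.074}
  f_instab_HTO:  {mean: 0.095, sd: 0.0190, low: 0.076, high: 0.114}
  p_periop_death: {mean: 0.0, sd: 0.0}
utilities:
  u_well_TKA:     {mean: 0.840, sd: 0.150}
  u_well_UKA:     {mean: 0.870, sd: 0.130}
  u_well_HTO:     {mean: 0.835, sd: 0.167}
  u_fail_TKA:     {mean: 0.610, sd: 0.200}
  u_fail_UKA:     {mean: 0.690, sd: 0.140}
  u_fail_HTO:     {mean: 0.690, sd: 0.140}
  u_fail_instab:  {mean: 0.500, sd: 0.300}
  u_post_rev1:    {mean: 0.772, sd: 0.154}
  u_tka_after_hto: {mean: 0.804, sd: 0.161}
  u_post_vvc:     {mean: 0.740, sd: 0.180}
fees:
  fee_TKA:    {mean: 1146, sd: 229, low: 0, high: 1548}
  fee_TKA_hw: {mean: 1299, sd: 259, low: 0, high: 1752}
  fee_UKA:    {mean: 1067, sd: 213, low: 0, high: 1440}
  fee_HTO:    {mean: 950,  sd: 190, low: 0, high: 1283}
  fee_revTKA: {mean: 1547, sd: 309, low: 0, high: 2088}
costs:
  cost_TKA:         {mean: 8010,  sd: 1738, low: 0, high: 11067}
  cost_UKA:         {mean: 8272,  sd: 738,  low: 0, high: 9523}
  cost_HTO:         {mean: 8091,  sd: 2929, low: 0, high: 13433}
  cost_rev_primary: {mean: 8178,  sd: 1636, low: 0, high: 11041}
  cost_rev_vvc:     {mean: 14739, sd: 2948, low: 0, high: 19899}
model:
  annual_discount: 0.015
  wtp_per_qalm: 4166.67
  start_age_months: 540
  horizon_cycles: 540
  psa_iterations: 3000
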