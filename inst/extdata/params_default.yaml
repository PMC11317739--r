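start_age: 64.599999999999994
male_fraction: 0.67
p_recur_first: 0.268
rr_recur_reablation: 1.61
p_reablate_2nd: 0.78
p_reablate_3rd: 0.37
mix_2nd_rfa_after_rfa: 0.983
mix_2nd_rfa_after_cba: 0.964
mix_3rd_rfa_after_rfa: 0.979
mix_3rd_rfa_after_cba: 1.0
sae_probs_rfa:
  esophageal: 0.005
  tamponade: 0.01
  pv_stenosis: 0.01
  phrenic_palsy: 0.0
  vascular: 0.02
  groin: 0.01
sae_probs_cba:
  esophageal: 0.005
  tamponade: 0.004
  pv_stenosis: 0.01
  phrenic_palsy: 0.01
  vascular: 0.02
  groin: 0.01
p_is_tree: 0.007
p_death_tree: 0.012
p_recur_markov_y12: 0.077
p_recur_markov_later: 0.041
p_is_markov: 0.0024
p_is_death_28d: 0.073
p_is_death_1y_survivors: 0.127
p_death_post_is: 0.085
cost_proc_rfa: 2256516.0
cost_proc_cba: 2609223.0
sae_costs:
  esophageal: 3261455.0
  tamponade: 160598.0
  pv_stenosis: 1679342.0
  phrenic_palsy: 15230.0
  vascular: 107065.0
  groin: 107065.0
cost_is_nonfatal: 1127624.0
cost_is_fatal: 2429749.0
cost_state_af_pos: 172780.0
cost_state_af_neg: 36373.0
cost_state_post_is: 67486.0
discount_rate: 0.02
jpy_per_usd: 150.0
dsa_ranges:
  start_age:
  - 63.899999999999999
  - 65.299999999999997
  male_fraction:
  - 0.638
  - 0.702
  p_recur_first:
  - 0.214
  - 0.322
  rr_recur_reablation:
  - 1.29
  - 1.93
  p_reablate_2nd:
  - 0.735
  - 0.825
  p_reablate_3rd:
  - 0.214
  - 0.526
  mix_2nd_rfa_after_rfa:
  - 0.978
  - 0.988
  mix_2nd_rfa_after_cba:
  - 0.952
  - 0.976
  mix_3rd_rfa_after_rfa:
  - 0.961
  - 0.997
  sae_prob_esophageal:
  - 0.004
  - 0.006
  sae_prob_tamponade_rfa:
  - 0.008
  - 0.012
  sae_prob_tamponade_cba:
  - 0.003
  - 0.005
  sae_prob_pv_stenosis:
  - 0.008
  - 0.012
  sae_prob_phrenic_palsy_cba:
  - 0.008
  - 0.012
  sae_prob_vascular:
  - 0.016
  - 0.024
  sae_prob_groin:
  - 0.008
  - 0.012
  p_is_tree:
  - 0.006
  - 0.008
  p_death_tree:
  - 0.01
  - 0.014
  p_recur_markov_y12:
  - 0.062
  - 0.092
  p_recur_markov_later:
  - 0.033
  - 0.049
  p_is_markov:
  - 0.002
  - 0.003
  p_is_death_28d:
  - 0.058
  - 0.088
  p_is_death_1y_survivors:
  - 0.102
  - 0.152
  p_death_post_is:
  - 0.068
  - 0.102
  cost_proc_rfa:
  - 2247957.0
  - 2265075.0
  cost_proc_cba:
  - 2600718.0
  - 2617728.0
  sae_cost_esophageal:
  - 2067117.0
  - 4455793.0
  sae_cost_tamponade:
  - 157987.0
  - 163211.0
  sae_cost_pv_stenosis:
  - 1152122.0
  - 2206562.0
  sae_cost_phrenic_palsy:
  - 12184.0
  - 18276.0
  sae_cost_vascular:
  - 105325.0
  - 108807.0
  sae_cost_groin:
  - 105325.0
  - 108807.0
  cost_is_nonfatal:
  - 862765.0
  - 1392483.0
  cost_is_fatal:
  - 179672.0
  - 4679826.0
  cost_state_af_pos:
  - 138224.0
  - 207336.0
  cost_state_af_neg:
  - 33975.0
  - 38771.0
  cost_state_post_is:
  - 21579.0
  - 113393.0
  discount_rate:
  - 0.0
  - 0.04

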