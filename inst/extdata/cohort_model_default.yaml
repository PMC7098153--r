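# Default component model for the synthetic two-wave cohort generator.
# Values are chosen so that the published ELSA wave-2 thresholds sit at
# roughly the 20th percentile of each sex-specific adjusted distribution,
# with a small gap either side of the cut so that cohort-derived quintile
# thresholds reproduce the intended deficit flags.
#
# grip/gait blocks give the distribution of the *adjusted* measure
# (truncated normal) for participants flagged low (below cut - gap) and not
# flagged (above cut + gap); raw measures are reconstructed through the
# BMI/height adjustment formulas.
grip:
  male:    {mean: 38.0, sd: 7.0,  lo: 8.0, hi: 70.0}
  female:  {mean: 23.0, sd: 5.5,  lo: 4.0, hi: 45.0}
  gap: 0.3
gait:
  male:    {mean: 0.90, sd: 0.26, lo: 0.30, hi: 1.80}
  female:  {mean: 0.82, sd: 0.24, lo: 0.30, hi: 1.70}
  gap: 0.010
bmi:
  mean: 27.5
  sd: 4.5
  lo: 19.0
  hi: 45.0
  low_lo: 16.2     # range used when the weight-loss flag takes the low-BMI route
  low_hi: 18.4
height:
  male:    {mean: 172.0, sd: 7.0, lo: 155.0, hi: 198.0}
  female:  {mean: 158.0, sd: 6.5, lo: 142.0, hi: 185.0}
age:
  mean: 70.8
  sd: 7.9
  lo: 60.0
  hi: 95.0
weight_loss:
  bmi_route_prob: 0.35   # P(flag realised through BMI < 18.5 rather than >10% loss)
  loss_flag_lo: 0.105    # weight-loss fraction when flagged through the loss route
  loss_flag_hi: 0.22
  loss_ok_lo: -0.08      # weight change when not flagged (gain of 8% to loss < 10%)
  loss_ok_hi: 0.095
  prior_missing: 0.10    # P(prior-wave weight missing) outside the loss route
exhaustion:
  # answer pattern probabilities (effort, get_going) given the flag is set
  yes_yes: 0.50
  yes_no: 0.25
  no_yes: 0.25
# activity frequency triples (mild, moderate, vigorous) with their index
# value; low combinations all score below both sex cuts (13.5/16.5), high
# combinations all score at or above 18 units.
activity_low:
  - {mild: never,       moderate: never,       vigorous: never, prob: 0.15}  # 0
  - {mild: monthly_1_3, moderate: never,       vigorous: never, prob: 0.20}  # 3
  - {mild: never,       moderate: monthly_1_3, vigorous: never, prob: 0.20}  # 6
  - {mild: monthly_1_3, moderate: monthly_1_3, vigorous: never, prob: 0.25}  # 9
  - {mild: weekly_1,    moderate: monthly_1_3, vigorous: never, prob: 0.20}  # 12
activity_high:
  - {mild: weekly_1,   moderate: weekly_1,   vigorous: never,       prob: 0.25}  # 18
  - {mild: weekly_gt1, moderate: weekly_1,   vigorous: never,       prob: 0.20}  # 24
  - {mild: weekly_1,   moderate: weekly_1,   vigorous: monthly_1_3, prob: 0.20}  # 30
  - {mild: weekly_gt1, moderate: weekly_gt1, vigorous: weekly_1,    prob: 0.15}  # 60
  - {mild: weekly_gt1, moderate: weekly_gt1, vigorous: weekly_gt1,  prob: 0.20}  # 84
# share of the expected total deficit count carried by each component
# (grip and gait calibrated so their marginal flag rate is 20% under the
# default baseline category mix, keeping quintile-derived cuts
# self-consistent).
flag_share:
  weight_loss: 0.084
  exhaustion: 0.284
  low_grip: 0.218
  low_gait: 0.218
  low_activity: 0.196
male_fraction: 0.551
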