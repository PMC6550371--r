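# Six simulation scenarios: three plausible pamidronate truths, each with a
# no-difference case and a clinically-relevant-margin case (mu_A = mu_P / 1.3).
- label: A_null
  mu_P_mm: -32.3
  mu_A_mm: -32.3
  sigma_mm: 9.3
  n_per_arm: 20
- label: A_relevant
  mu_P_mm: -32.3
  mu_A_mm: -24.9
  sigma_mm: 9.3
  n_per_arm: 20
- label: B_null
  mu_P_mm: -40
  mu_A_mm: -40
  sigma_mm: 11.5
  n_per_arm: 20
- label: B_relevant
  mu_P_mm: -40
  mu_A_mm: -30.8
  sigma_mm: 11.5
  n_per_arm: 20
- label: C_null
  mu_P_mm: -26
  mu_A_mm: -26
  sigma_mm: 7.5
  n_per_arm: 20
- label: C_relevant
  mu_P_mm: -26
  mu_A_mm: -20
  sigma_mm: 7.5
  n_per_arm: 20
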