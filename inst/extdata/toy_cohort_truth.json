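{
  "note": "Hand-computed nonparametric standardization for the synthetic toy cohort: psi_a = sum_w Phat(W=w) * mean(Y | A=a, W=w). With P(W=0)=P(W=1)=1/2 and cell means 1/3,2/3,2/3 (w=0) and 1/3,1/3,2/3 (w=1): psi_low=1/3, psi_medium=1/2, psi_high=2/3.",
  "hand_psi": {
    "low": 0.3333333333333333,
    "medium": 0.5,
    "high": 0.6666666666666666
  },
  "hand_ate": {
    "high_vs_low": 0.3333333333333333,
    "high_vs_medium": 0.16666666666666666,
    "medium_vs_low": 0.16666666666666666
  }
}
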