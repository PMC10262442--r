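# Example analysis configuration: aggregate index, all four ANC outcome
# specifications, the fast penalized-linear library, no stratification.
indices: [aggregate]
outcomes: [ge4_vs_1to3, none_vs_1to3, ge4_vs_none, count]
learners: [glm, lasso, ridge]
n_folds: 10
seed: 2019
g_bounds: [0.025, 0.975]
stratify: false
gcomp: true
n_boot: 200
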