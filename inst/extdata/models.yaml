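# Default candidate model space for AICc model-selection voting.
# Five base exposure variants (single metrics, the two-metric and the
# three-metric log-sum composites) crossed with covariate subsets of up
# to two terms. The published analysis reports a 237-model family whose
# exact enumeration is not reconstructible from its description; this
# space is the package default and the multiplicity-correction family
# size is configurable independently (see ?vote_models).
bases:
  - logInhEC
  - logResEC
  - logSC
  - logInhResEC
  - logSumExp
covariates:
  - logIL6
  - logCCL2
  - logTNFalpha
  - logVCAM
  - logICAM
  - age_bin
  - duration_bin
  - sex
  - solvent_current
  - solvent_past
max_covariates: 2
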