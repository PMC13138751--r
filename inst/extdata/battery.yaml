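# Eco-evolutionary hypothesis battery for handedness direction/strength.
# Each entry is a named covariate set; the engine treats this file purely
# as data, so sets can be edited or extended without touching code.
brain_size:
  covariates: [ECV]
  applies_to: both
bipedalism_locomotor:
  covariates: [IMI, SUBS]
  applies_to: both
tool_use_social_organisation: # TU-SH-SSH
  covariates: [TOOL, SOC_SYS, ECV]
  applies_to: both
substrate_social_bipedal_tool: # SP-SS-B-TUH
  covariates: [SUBS, SOC_SYS, IMI, TOOL, BM]
  applies_to: both
fighting:
  covariates: [DIM, CL]
  applies_to: both
extractive_foraging:
  covariates: [EXT, DIET]
  applies_to: both
frugivory:
  covariates: [FRUIT, BM]
  applies_to: both
social_learning:
  covariates: [SOC_LEARN, ECV]
  applies_to: both
task_complexity:
  covariates: [TOOL, EXT, ECV]
  applies_to: both
allometry:
  covariates: [BM, ECV, DIM]
  applies_to: both
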