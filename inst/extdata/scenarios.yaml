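# Model-scenario registry: one entry per row of the experiment grid.
#
# filters:      "standard" (5 h / 10 km / 10 observers), "none"
# balancing:    hexagonal spatial balancing of checklists (1-km grid)
# effort_model: checklist detection via saturating effort function
#               (FALSE = intercept-only, equal detection across checklists)
# false_positive_on / covariate_integration: which dataset (if any) gets the
#               false-positive observation model, or is summarized into
#               buffer covariates and removed from the joint likelihood
# holdout_pool: which records are eligible for cross-validation holdout
scenarios:
  - id: R1
    family: effort
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F1
    family: effort
    reference: R1
    filters: none
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F2
    family: effort
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: false
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F3
    family: effort
    reference: R1
    filters: none
    exclude_traveling: false
    balancing: false
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F4
    family: effort
    reference: R1
    filters: standard
    exclude_traveling: true
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F5
    family: effort
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: false
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: F6
    family: effort
    reference: R1
    filters: none
    exclude_traveling: false
    balancing: false
    effort_model: false
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: E1
    family: reliability
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: checklist
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: E2
    family: reliability
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: checklist
    drop_checklist: false
    uses_historic: false
    holdout_pool: structured_only
  - id: E3
    family: reliability
    reference: R1
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: true
    uses_historic: false
    holdout_pool: structured_only
  - id: R2
    family: reliability
    reference: R2
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: true
    holdout_pool: current_only
  - id: O1
    family: reliability
    reference: R2
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: historic
    covariate_integration: ~
    drop_checklist: false
    uses_historic: true
    holdout_pool: current_only
  - id: O2
    family: reliability
    reference: R2
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: historic
    drop_checklist: false
    uses_historic: true
    holdout_pool: current_only
  - id: O3
    family: reliability
    reference: R2
    filters: standard
    exclude_traveling: false
    balancing: true
    effort_model: true
    false_positive_on: ~
    covariate_integration: ~
    drop_checklist: false
    uses_historic: false
    holdout_pool: current_only
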