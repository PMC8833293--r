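# Shared fixtures: small, fast study configurations built in code.

# compact configuration for pipeline tests; fs = 1600 keeps the HFO band
# below Nyquist while making signal synthesis and filtering cheap
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 1, hemispheres_per_patient = 2,
                   fs = 1600, rest_duration = 3,
                   burst_protocol = stim_protocol(duration_s = 3),
                   seed = 101L)
  do.call(study_config, utils::modifyList(defaults, args))
}

# deterministic hemisphere parameters with well-separated distances
quick_hp <- function(...) {
  args <- list(...)
  defaults <- list(distances = c(6, 3.5, 1, 2.2))
  do.call(hemisphere_params, utils::modifyList(defaults, args))
}

# cohort-characteristics fixture: per-patient postoperative UPDRS III
# improvement (%)
updrs_improvements <- function() {
  read.csv(system.file("extdata", "updrs_improvement_pct.csv",
                       package = "ernarank"))$improvement_pct
}

rms <- function(x) sqrt(mean(x^2))
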