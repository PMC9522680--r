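# Shared fixtures: small designs and quiet (low/zero noise) generator
# parameters, built in code so every test is self-contained.

small_design <- function(n_subjects = 8L) study_design(n_subjects = n_subjects)

quiet_params <- function(seed = 1L, cv_between = 0, cv_within = 0,
                         true_means = default_true_means()) {
  generation_params(true_means = true_means, cv_between = cv_between,
                    cv_within = cv_within,
                    sham_background = c(formaldehyde = 0),
                    seed = seed)
}

# true means with a single common value for every product of one analyte
flat_means <- function(value = 150) {
  m <- default_true_means()
  m["nicotine", ] <- value
  m
}
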