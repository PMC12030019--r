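# The lead-time / parameter-recovery study and the irrigation-policy
# comparison are expensive (they train the 3-member ensemble), so their
# results are computed once per test run and shared across test blocks.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- lead_time_study(seed = 101L, n_eval = 20L)
  }
  .study_cache$study
}

cached_policy_comparison <- function() {
  if (is.null(.study_cache$policies)) {
    st <- cached_study()
    .study_cache$policies <- compare_policies(st$checkpoints, seed = 301L)
  }
  .study_cache$policies
}
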