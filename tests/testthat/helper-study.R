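# The scaled scenario study is the expensive shared fixture of the
# simulation-level tests (all 10 canonical scenarios, reduced to at most
# ~3000 fibers with ratios preserved, 10 seeded replicates each, default
# surrogate kinetics, bind_prob 1). It is run once per test session and
# reused by every test that needs it.

.study_cache <- new.env(parent = emptyenv())

scaled_study_fixture <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_scaled_study(
      max_fibers = 3000, n_replicates = 10, seed = 1,
      record_interval = 10, bind_prob = 1
    )
    .study_cache$headlines <- study_headlines(.study_cache$study)
  }
  .study_cache
}
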