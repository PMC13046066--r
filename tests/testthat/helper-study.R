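# Shared full-protocol study run (all six dataset variants, both models,
# replicate seeds 0-9, n = 10 000), computed once per test session and
# reused by the acceptance tests.
.study_cache <- new.env(parent = emptyenv())

study_report <- function() {
  if (is.null(.study_cache$report)) {
    .study_cache$report <- run_replicated_experiment(
      categories = c("soft", "bone"), snrs = c(Inf, 10, 5),
      models = c("lm", "nn"), seeds = 0:9, n = 10000L
    )
  }
  .study_cache$report
}

study_cell <- function(report, category, snr, model, element) {
  s <- report$summary
  s[s$category == category & s$snr == snr & s$model == model &
      s$element == element, ]
}
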