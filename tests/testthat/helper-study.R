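# The desk-scale end-to-end study (600 synthetic images: 400 train /
# 100 validation / 100 test, T = 100 MC passes) takes several minutes, so it
# is run once per test session and cached for every test that inspects it.
study_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(study_cache$study)) {
    study_cache$study <- suppressWarnings(
      run_synthetic_study(
        n_train = 400L, n_validation = 100L, n_test = 100L,
        T_mc = 100L, seed = 2024L
      )
    )
  }
  study_cache$study
}
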