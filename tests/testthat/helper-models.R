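# Shared fixtures: everything is built in code at test time.

# the bundled base-case spec is used across many files; build it once
paper_spec_cache <- new.env(parent = emptyenv())

paper_spec <- function() {
  if (is.null(paper_spec_cache$spec)) {
    paper_spec_cache$spec <- thyroid_screening_spec()
  }
  paper_spec_cache$spec
}

# PSA scatters over several seeds are expensive; computed once and shared
# between the probability and acceptability-curve checks
psa_scatters <- function(n_seeds = 10L, n_draws = 1000L) {
  key <- sprintf("s%d_d%d", n_seeds, n_draws)
  if (is.null(paper_spec_cache[[key]])) {
    spec <- paper_spec()
    paper_spec_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      run_psa(spec, n_draws = n_draws, seed = s)
    })
  }
  paper_spec_cache[[key]]
}

# a small scatter assembled by hand for the counting checks
manual_scatter <- function(dqaly, dcost) {
  df <- data.frame(draw = seq_along(dqaly), dqaly = dqaly, dcost = dcost)
  class(df) <- c("psa_scatter", class(df))
  attr(df, "n_draws") <- nrow(df)
  df
}

expect_no_violations <- function(spec) {
  testthat::expect_identical(validate_model(spec), character(0))
}
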