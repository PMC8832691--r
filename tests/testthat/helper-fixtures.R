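# Shared fixtures. Everything is generated in code; no binary files.

# open square field of half-size h mm at the isocentre plane
square_beam <- function(h = 75, mu = 100) {
  cps <- list(
    controlPoint(0, 0, rep(h, 60), rep(-h, 60), c(-h, h), c(-h, h)),
    controlPoint(1, 1, rep(h, 60), rep(-h, 60), c(-h, h), c(-h, h)))
  beamField("open", mu, cps)
}

# the 128 x 96 analysis-grid geometry used in desk-scale runs
quick_grid <- function(margin = 8L) epidGrid(128L + 2L * margin,
                                             96L + 2L * margin, 400 / 128)

# memoised desk-scale end-to-end run shared by the acceptance tests (the
# expensive part: dataset generation + network training)
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runExperiment(quicktestConfig())
    cache
  }
})
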