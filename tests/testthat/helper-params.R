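# shared fixtures: all parameter sets are built in code

# flat (no circadian modulation) two-process set with known closed-form
# episode durations: wake = 18 log 3, sleep = 4 log 3
flat_two_process <- function() {
  two_process_params(mu = 1, H0_plus = 0.75, H0_minus = 0.25,
                     chi_w = 18, chi_s = 4,
                     circadian = circadian_waveform(0))
}

# session-scoped cache for expensive fixtures shared across test files
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# a converged 12-day run of the full sigmoid human model
human_pr_sim <- function() {
  cached("human_pr_sim", simulate_pr(pr_human(), t_span = 24 * 12, init = "wake"))
}

# wake-effort comparisons at human defaults (linear and saturating forms)
human_effort_linear <- function() {
  cached("effort_linear",
         wake_effort_compare(pr_human(), days = 4,
                             calibration = sleepdyn:::human_calibration()))
}

human_effort_saturating <- function() {
  cached("effort_saturating",
         wake_effort_compare(pr_human(asymptote_form = "saturating"), days = 4))
}
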