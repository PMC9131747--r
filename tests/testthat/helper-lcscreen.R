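# Shared fixtures: the base-case parameter set is loaded once per test run;
# small cohort layouts keep the model evaluations fast.

base_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- lcscreen::default_parameter_set()
    p
  }
})

one_cohort <- function(age = 60) cohorts_at_age(age, n_cohorts = 1)

# the 2-state geometric toy: p(Death) = 0.5 per cycle, unit utility
geometric_chain <- function(p_death = 0.5) {
  ch <- make_toy_chain(2, seed = 1)
  ch$P <- matrix(c(1 - p_death, p_death, 0, 1), 2, 2, byrow = TRUE)
  ch$cost <- c(0, 0)
  ch$utility <- c(1, 0)
  ch
}
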