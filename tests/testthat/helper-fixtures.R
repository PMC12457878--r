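# Shared fixtures: the packaged 27-worker validation roster and a random
# roster generator for property-style tests.

t3 <- table3_roster()
t3_assessed <- assess_cohort(t3)

# uniformly random but valid exposure records
random_roster <- function(n, seed) {
  set.seed(seed)
  data.frame(
    worker_id = sprintf("R%04d", seq_len(n)),
    concentration_ppm = runif(n, 0, 20),
    weight_kg = runif(n, 40, 110),
    hours_per_day = runif(n, 1, 24),
    days_per_year = runif(n, 100, 365),
    tenure_years = runif(n, 0, 40),
    stringsAsFactors = FALSE
  )
}
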