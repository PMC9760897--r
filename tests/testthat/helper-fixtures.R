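# Fixtures built in code at test time.

logistic_series <- function(n, r = 3.8, x0 = 0.31, id = "lm") {
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  replicate_series(id, 0:(n - 1), matrix(x, ncol = 1,
                                         dimnames = list(NULL, "x")))
}

toy_csv <- function(path) {
  writeLines(c(
    "replicate_id,time,prey,predator",
    "r1,0,5,2", "r1,1,7,3", "r1,2,6,5",
    "r2,0,8,1", "r2,1,9,2", "r2,2,4,6"), path)
  path
}

pp_roles <- c(prey = "prey", predator = "predator")

# Two Lotka-Volterra regimes with initial abundances on opposite sides of
# the prey = 10 line; regime 2 has stronger predation and conversion, so
# dynamics differ between groups while being shared within each.
two_regime_dataset <- function(seed, sigma = 0.05, n_steps = 50,
                               n_per_group = 3) {
  set.seed(seed)
  n0_a <- lapply(seq_len(n_per_group),
                 function(i) c(4 + 1.2 * i, 8 + stats::runif(1, -1, 1)))
  n0_b <- lapply(seq_len(n_per_group),
                 function(i) c(12 + 1.2 * i, 8 + stats::runif(1, -1, 1)))
  a <- simulate_lv_replicates(n0_a, params = list(a = 1, b = 0.1,
                                                  c = 0.05, d = 0.5),
                              sigma = sigma, n_steps = n_steps, step = 0.5,
                              name = "regime1")
  b <- simulate_lv_replicates(n0_b, params = list(a = 1, b = 0.25,
                                                  c = 0.12, d = 0.5),
                              sigma = sigma, n_steps = n_steps, step = 0.5,
                              name = "regime2")
  b$replicates <- lapply(b$replicates, function(r) {
    r$replicate_id <- sub("lv", "mv", r$replicate_id)
    r
  })
  b <- edm_dataset("regime2", unname(b$replicates), b$step)
  bind_datasets(a, b, name = "two_regime")
}
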