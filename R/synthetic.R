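#' Simulate a discrete-time single-species growth map with process noise
#'
#' Two classic forms are available. The Ricker map
#' `x(t+1) = x(t) * exp(r * (1 - x(t))) * exp(sigma * z(t))` with standard
#' normal `z` uses multiplicative log-normal process noise, which keeps
#' abundances positive; it is chaotic for growth rates above roughly 2.69,
#' so r = 3 gives deterministic chaos. The quadratic logistic map
#' `x(t+1) = r * x(t) * (1 - x(t)) + sigma * z(t)` (clipped to [0, 1]) is
#' the textbook chaotic map at r = 4 with Lyapunov exponent log 2; growth
#' rates above 4 escape the unit interval and are rejected.
#'
#' @param model `"ricker"` or `"quadratic"`.
#' @param r Growth rate.
#' @param sigma Process-noise standard deviation per step (>= 0); 0 gives
#'   an exactly deterministic trajectory.
#' @param n_steps Number of retained time steps (>= 2).
#' @param x0 Initial abundance; `NULL` draws it uniformly from (0.1, 0.9).
#' @param burn_in Steps discarded before recording starts (default 0).
#' @param seed Integer seed; fixing it makes the output byte-identical.
#' @param replicate_id Id for the returned series.
#' @param observation_noise_sd Additive Gaussian observation noise applied
#'   after simulation, floored at 0 (default 0).
#' @return A single-species [replicate_series()] on the grid 0, 1, ...,
#'   `n_steps - 1` (days).
#' @export
simulate_map <- function(model = c("ricker", "quadratic"), r, sigma = 0,
                         n_steps = 100, x0 = NULL, burn_in = 0,
                         seed = NULL, replicate_id = "sim",
                         observation_noise_sd = 0) {
  model <- match.arg(model)
  stopifnot(sigma >= 0, n_steps >= 2, burn_in >= 0)
  if (model == "quadratic" && r > 4) {
    stop("quadratic logistic map escapes [0, 1] for r > 4")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- stats::runif(1, 0.1, 0.9)
  total <- n_steps + burn_in
  x <- numeric(total)
  x[1] <- x0
  z <- if (sigma > 0) stats::rnorm(total - 1) else numeric(total - 1)
  for (t in seq_len(total - 1)) {
    x[t + 1] <- step_map(model, x[t], r, sigma, z[t])
  }
  x <- x[(burn_in + 1):total]
  if (observation_noise_sd > 0) {
    x <- pmax(x + stats::rnorm(n_steps, sd = observation_noise_sd), 0)
  }
  replicate_series(replicate_id, 0:(n_steps - 1),
                   matrix(x, ncol = 1, dimnames = list(NULL, "x")))
}

step_map <- function(model, x, r, sigma, z) {
  if (model == "ricker") {
    x * exp(r * (1 - x)) * exp(sigma * z)
  } else {
    min(max(r * x * (1 - x) + sigma * z, 0), 1)
  }
}

#' Simulate replicated stochastic Lotka-Volterra predator-prey dynamics
#'
#' All replicates share one parameterization of the Lotka-Volterra system
#' dprey/dt = prey * (a - b * predator), dpredator/dt = predator *
#' (c * prey - d), and differ only in their initial abundances - the
#' experimental design of replicated microcosms started at distinct points
#' in phase space. Integration is Euler-Maruyama at internal step `dt` with
#' additive process noise of standard deviation `sigma` per unit time on
#' each species, recorded every `step` days; abundances are floored at 0,
#' so trajectories driven to extinction stay extinct.
#'
#' @param N0_list List of initial abundance vectors `c(prey, predator)`,
#'   one per replicate.
#' @param params List with positive rates `a` (prey growth), `b`
#'   (predation), `c` (conversion), `d` (predator mortality).
#' @param sigma Process-noise sd (>= 0).
#' @param n_steps Number of recorded time points per replicate.
#' @param step Recording interval in days (> 0).
#' @param dt Internal integration step (> 0, <= step).
#' @param seed Integer seed for reproducibility.
#' @param name Dataset name.
#' @return An [edm_dataset()] of `length(N0_list)` replicates on a common
#'   regular grid, with species `prey` and `predator` and matching roles.
#' @export
simulate_lv_replicates <- function(N0_list,
                                   params = list(a = 1, b = 0.1,
                                                 c = 0.05, d = 0.5),
                                   sigma = 0, n_steps = 60, step = 0.5,
                                   dt = 0.05, seed = NULL,
                                   name = "lv") {
  stopifnot(length(N0_list) >= 1, sigma >= 0)
  if (step <= 0 || dt <= 0 || dt > step) {
    stop("need 0 < dt <= step")
  }
  if (any(unlist(params) <= 0)) stop("all Lotka-Volterra rates must be > 0")
  sub <- round(step / dt)
  if (abs(sub * dt - step) > 1e-9) stop("step must be a multiple of dt")
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_along(N0_list), function(i) {
    n0 <- as.numeric(N0_list[[i]])
    stopifnot(length(n0) == 2, all(n0 >= 0))
    out <- matrix(0, nrow = n_steps, ncol = 2,
                  dimnames = list(NULL, c("prey", "predator")))
    state <- n0
    out[1, ] <- state
    for (k in 2:n_steps) {
      for (s in seq_len(sub)) {
        drift <- c(state[1] * (params$a - params$b * state[2]),
                   state[2] * (params$c * state[1] - params$d))
        noise <- if (sigma > 0) sigma * sqrt(dt) * stats::rnorm(2) else c(0, 0)
        state <- pmax(state + drift * dt + noise, 0)
      }
      out[k, ] <- state
    }
    replicate_series(paste0("lv", i), step * (0:(n_steps - 1)), out,
                     roles = c(prey = "prey", predator = "predator"))
  })
  edm_dataset(name, reps, step)
}

#' Simulate a stationary first-order vector autoregression
#'
#' `x(t+1) = A x(t) + e(t)` with iid Gaussian innovations; the first
#' `burn_in` steps are discarded so the retained series is (approximately)
#' stationary. A linear benchmark: the S-map at theta = 0 should recover
#' `A` as its coefficient matrix.
#'
#' @param A Square coefficient matrix with spectral radius < 1.
#' @param sd Innovation standard deviation (>= 0).
#' @param n Retained series length.
#' @param seed Integer seed.
#' @param burn_in Discarded initial steps (default 100).
#' @param x0 Initial state vector (default the origin).
#' @return A [replicate_series()] with one species per dimension of `A`.
#' @export
simulate_var1 <- function(A, sd = 0.01, n = 500, seed = NULL,
                          burn_in = 100, x0 = NULL) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), sd >= 0, n >= 2)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("unstable VAR: spectral radius of A must be < 1")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(A)
  total <- n + burn_in
  x <- matrix(0, nrow = total, ncol = k)
  if (!is.null(x0)) x[1, ] <- x0
  for (t in seq_len(total - 1)) {
    innov <- if (sd > 0) stats::rnorm(k, sd = sd) else numeric(k)
    x[t + 1, ] <- drop(A %*% x[t, ]) + innov
  }
  x <- x[(burn_in + 1):total, , drop = FALSE]
  # a VAR fluctuates around 0; shift up so abundances stay nonnegative
  if (min(x) < 0) x <- x - min(x)
  colnames(x) <- paste0("x", seq_len(k))
  replicate_series("var1", 0:(n - 1), x)
}

#' Brute-force Lyapunov exponent of a deterministic map
#'
#' Independent of any forecasting machinery: pairs of trajectories are
#' started a distance `delta0` apart (after a burn-in that places them on
#' the attractor) and iterated for `T_steps` steps — short enough that the
#' separation stays far from saturation — and the exponent is the mean of
#' `log(|x(T) - x'(T)| / delta0) / T` over pairs. For the quadratic
#' logistic map at r = 4 the analytic value is log 2.
#'
#' @param model `"ricker"` or `"quadratic"` (deterministic only; the
#'   divergence of noisy trajectories does not define a Lyapunov exponent).
#' @param r Growth rate.
#' @param n_pairs Number of trajectory pairs (>= 1).
#' @param delta0 Initial separation (default 1e-8).
#' @param T_steps Divergence window in steps (default 10).
#' @param burn_in Steps used to reach the attractor before perturbing.
#' @param seed Integer seed.
#' @param sigma Must be 0; nonzero noise is rejected.
#' @return Scalar Lyapunov exponent estimate (per step).
#' @export
lyapunov_oracle <- function(model = c("ricker", "quadratic"), r,
                            n_pairs = 1000, delta0 = 1e-8, T_steps = 10,
                            burn_in = 50, seed = NULL, sigma = 0) {
  model <- match.arg(model)
  if (sigma != 0) {
    stop("the divergence oracle is defined for deterministic maps only")
  }
  stopifnot(n_pairs >= 1, delta0 > 0, T_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  x0s <- stats::runif(n_pairs, 0.1, 0.9)
  lams <- vapply(x0s, function(x) {
    for (t in seq_len(burn_in)) x <- step_map(model, x, r, 0, 0)
    xp <- x + delta0
    for (t in seq_len(T_steps)) {
      x <- step_map(model, x, r, 0, 0)
      xp <- step_map(model, xp, r, 0, 0)
    }
    sep <- abs(x - xp)
    if (sep == 0) return(NA_real_)
    log(sep / delta0) / T_steps
  }, numeric(1))
  if (anyNA(lams)) {
    warning(sum(is.na(lams)), " pair(s) collapsed to zero separation; dropped")
  }
  mean(lams, na.rm = TRUE)
}
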