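# Independent brute-force reference implementations used as oracles.
# Deliberately written with explicit loops, explicit sorting, and stats::lm
# (a different least-squares route than the package's SVD solver).

oracle_simplex <- function(lib_rows, lib_targets, query, k = ncol(lib_rows) + 1) {
  d <- numeric(nrow(lib_rows))
  for (i in seq_len(nrow(lib_rows))) {
    d[i] <- sqrt(sum((lib_rows[i, ] - query)^2))
  }
  ord <- sort.int(d, index.return = TRUE)$ix[seq_len(k)]
  dn <- d[ord]
  tn <- lib_targets[ord]
  if (dn[1] == 0) return(mean(tn[dn == 0]))
  w <- exp(-dn / dn[1])
  sum(w * tn) / sum(w)
}

oracle_smap <- function(lib_rows, lib_targets, query, theta) {
  d <- numeric(nrow(lib_rows))
  for (i in seq_len(nrow(lib_rows))) {
    d[i] <- sqrt(sum((lib_rows[i, ] - query)^2))
  }
  w <- if (theta == 0) rep(1, length(d)) else exp(-theta * d / mean(d))
  df <- as.data.frame(lib_rows)
  names(df) <- paste0("v", seq_len(ncol(lib_rows)))
  df$y <- lib_targets
  fit <- stats::lm(y ~ ., data = df, weights = w)
  newd <- as.data.frame(matrix(query, nrow = 1))
  names(newd) <- paste0("v", seq_len(ncol(lib_rows)))
  unname(stats::predict(fit, newdata = newd))
}

# Direct two-trajectory divergence rate of a deterministic map (used to
# cross-check the forecast-error-based Lyapunov estimators).
oracle_divergence_rate <- function(step_fun, n_pairs, delta0 = 1e-8,
                                   T_steps = 10, burn_in = 50) {
  vals <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    x <- stats::runif(1, 0.1, 0.9)
    for (t in seq_len(burn_in)) x <- step_fun(x)
    xp <- x + delta0
    for (t in seq_len(T_steps)) {
      x <- step_fun(x)
      xp <- step_fun(xp)
    }
    vals[p] <- log(abs(x - xp) / delta0) / T_steps
  }
  mean(vals[is.finite(vals)])
}
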