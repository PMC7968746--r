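# Shared fixtures: small generating models used across the suite.

# two well-separated paths: T = (10, 80) ms, CV = (0.5, 0.2), p = (0.6, 0.4)
two_path_model <- function() {
  fp_model_from_summaries(tibble::tibble(
    mean_completion = c(10, 80),
    cv = c(0.5, 0.2),
    weight = c(0.6, 0.4)
  ))
}

exp_model <- function(tau = 10) fp_model(tau = tau, L = 1)

# dense 2-D log-grid quadrature of the M = 1 evidence
# ln P(D | M = 1) = ln \int\int P(D | tau, L) P(tau, L) dtau dL,
# independent of the importance-sampling path
quadrature_evidence_m1 <- function(data, priors = prior_config(),
                                   n_grid = 220,
                                   tau_range = c(1e-3, 400),
                                   L_range = c(1e-2, 200)) {
  occ <- fpinfer:::occupied_bins(data)
  lt <- seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid)
  lL <- seq(log(L_range[1]), log(L_range[2]), length.out = n_grid)
  logf <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    tau <- exp(lt[i])
    for (j in seq_len(n_grid)) {
      L <- exp(lL[j])
      lp <- -tau / priors$Z_tau - log(priors$Z_tau) -
        L / priors$Z_L - log(priors$Z_L)
      pr <- stats::pgamma(occ$hi, shape = L, scale = tau) -
        stats::pgamma(occ$lo, shape = L, scale = tau)
      ll <- sum(occ$n * log(pr))
      # integrate in (log tau, log L): Jacobian tau * L
      logf[i, j] <- ll + lp + log(tau) + log(L)
    }
  }
  m <- max(logf[is.finite(logf)])
  w <- exp(logf - m)
  w[!is.finite(w)] <- 0
  # trapezoid weights per dimension
  tw <- function(g) {
    d <- diff(g)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  }
  m + log(as.numeric(t(tw(lt)) %*% w %*% tw(lL)))
}
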