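# Independent oracles, written as straight-line transcriptions of the
# defining formulas so they share no code with the package internals.

# biweight midcorrelation: median/MAD weights evaluated step by step
oracle_bicor <- function(x, y) {
  weighted <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))          # unscaled MAD
    u <- (v - med) / (9 * madv)
    a <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    vt <- (v - med) * a
    vt / sqrt(sum(vt^2))
  }
  sum(weighted(x) * weighted(y))
}

# Efron partial log-likelihood for a single covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    d <- length(D)
    R <- which(time >= t)
    sR <- sum(exp(eta[R]))
    sD <- sum(exp(eta[D]))
    for (l in 0:(d - 1)) ll <- ll - log(sR - (l / d) * sD)
    ll <- ll + sum(eta[D])
  }
  ll
}

# brute-force maximizer (grid refine + optimize)
oracle_cox_beta <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) oracle_efron_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# a cohort data frame with exponential proportional hazards
make_ph_cohort <- function(n, betas = numeric(0), h0 = 0.05,
                           censor = Inf) {
  p <- length(betas)
  X <- matrix(rnorm(n * max(p, 1)), n, max(p, 1))
  colnames(X) <- if (p > 0) names(betas) else "G1"
  lp <- if (p > 0) as.vector(X %*% betas) else rep(0, n)
  t_ev <- rexp(n) / (h0 * exp(lp))
  t_c <- if (is.finite(censor)) runif(n, 0, censor) else rep(Inf, n)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             ttt_months = pmin(t_ev, t_c),
             ttt_event = as.integer(t_ev <= t_c),
             os_months = pmin(t_ev, t_c),
             os_event = as.integer(t_ev <= t_c),
             X, check.names = FALSE)
}

# two-group exponential survival data with a given hazard ratio
make_two_group <- function(n_per_group, hr, h0 = 0.05, censor = Inf) {
  labels <- factor(rep(c("low", "high"), each = n_per_group),
                   levels = c("low", "high"))
  rate <- ifelse(labels == "high", h0 * hr, h0)
  t_ev <- rexp(2 * n_per_group, rate)
  t_c <- if (is.finite(censor)) runif(2 * n_per_group, 0, censor) else Inf
  data.frame(ttt_months = pmin(t_ev, t_c),
             ttt_event = as.integer(t_ev <= t_c),
             os_months = pmin(t_ev, t_c),
             os_event = as.integer(t_ev <= t_c),
             labels = labels)
}

# small expression dataset with named rows
toy_expression <- function(values, id = "toy") {
  expression_dataset(as.matrix(values), id)
}
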