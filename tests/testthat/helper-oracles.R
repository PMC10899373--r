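# Independent oracles used across the suite. These deliberately avoid the
# package's own first-passage mathematics: the race simulator here is a plain
# Euler-Maruyama discretisation of the underlying diffusion, with a
# Brownian-bridge crossing correction that removes the leading discretisation
# bias at the boundary.

# Simulate n races between accumulators by time-stepping the diffusions.
# Returns choice (NA if no accumulator crossed before the horizon) and rt.
em_race <- function(n, drift, dist, t0 = 0, dt = 1e-3, horizon = 10) {
  n_acc <- length(drift)
  x <- matrix(0, n, n_acc)
  cross_t <- matrix(Inf, n, n_acc)
  sdt <- sqrt(dt)
  steps <- ceiling(horizon / dt)
  alive <- rep(TRUE, n)
  for (k in seq_len(steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    tnow <- k * dt
    for (a in seq_len(n_acc)) {
      live <- idx[is.infinite(cross_t[idx, a])]
      if (!length(live)) next
      x_old <- x[live, a]
      x_new <- x_old + drift[a] * dt + sdt * rnorm(length(live))
      crossed <- x_new >= dist[a]
      # Brownian bridge: probability the path crossed within the step even
      # though both endpoints are below the boundary
      if (any(!crossed)) {
        nb <- which(!crossed)
        pb <- exp(-2 * (dist[a] - x_old[nb]) *
                    pmax(dist[a] - x_new[nb], 0) / dt)
        crossed[nb] <- runif(length(nb)) < pb
      }
      cross_t[live[crossed], a] <- tnow
      x[live, a] <- x_new
    }
    alive[idx] <- rowSums(is.finite(cross_t[idx, , drop = FALSE])) == 0
  }
  choice <- apply(cross_t, 1, function(z)
    if (all(is.infinite(z))) NA_integer_ else which.min(z))
  rt <- cross_t[cbind(seq_len(n), ifelse(is.na(choice), 1L, choice))] + t0
  rt[is.na(choice)] <- NA_real_
  data.frame(choice = choice, rt = rt)
}

# Conjugate hierarchical normal toy: y_st ~ N(alpha_s, 1),
# alpha_s ~ N(mu, tau^2) with tau fixed, mu ~ N(0, 1).
make_normal_toy <- function(n_subj, n_obs, mu_true, tau, seed) {
  set.seed(seed)
  al <- rnorm(n_subj, mu_true, tau)
  dat <- lapply(seq_len(n_subj), function(s) rnorm(n_obs, al[s], 1))
  ll <- function(theta, d) {
    vapply(seq_len(nrow(theta)),
           function(i) sum(dnorm(d, theta[i, 1], 1, log = TRUE)), numeric(1))
  }
  model <- custom_model("m", dat, ll)
  prior <- group_prior("m")
  prior$mu0[] <- 0
  # analytic posterior of mu given the subject means
  yb <- vapply(dat, mean, numeric(1))
  v <- tau^2 + 1 / n_obs
  post_prec <- 1 + n_subj / v
  post_mean <- sum(yb) / v / post_prec
  # analytic log marginal likelihood of the full data
  N <- n_subj * n_obs
  y <- unlist(dat)
  Cov <- matrix(1, N, N)
  for (s in seq_len(n_subj)) {
    idx <- ((s - 1) * n_obs + 1):(s * n_obs)
    Cov[idx, idx] <- Cov[idx, idx] + tau^2
  }
  diag(Cov) <- diag(Cov) + 1
  logml <- -0.5 * (N * log(2 * pi) +
                     as.numeric(determinant(Cov, logarithm = TRUE)$modulus) +
                     as.numeric(t(y) %*% solve(Cov, y)))
  list(model = model, prior = prior, tau = tau, data = dat,
       post_mean = post_mean, post_sd = sqrt(1 / post_prec), logml = logml)
}

# Natural-scale generating group means of a cohort, for recovery checks.
truth_natural_mu <- function(trials) {
  truth <- attr(trials, "truth")
  co <- truth$cohort
  drop(to_natural_test(co$mu, co$layout$transforms))
}

to_natural_test <- function(x, transforms) {
  out <- x
  out[transforms == "log"] <- exp(x[transforms == "log"])
  out[transforms == "logit"] <- plogis(x[transforms == "logit"])
  out
}

# Reduced sampler settings for fast unit tests.
quick_config <- function(...) {
  sampler_config(burn = 60, adapt = 60, sample = 120,
                 particles = c(30, 30, 20), ...)
}
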