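#' Single-boundary diffusion (shifted Wald) first-passage-time density
#'
#' Density of the first-passage time of a drift-diffusion process with
#' within-trial noise \eqn{s = 1} through an absorbing boundary at distance
#' `dist` from the start point. This is the building block of the racing
#' diffusion model: each response option has one such accumulator and the
#' fastest one determines the response. Negative drifts are allowed, in which
#' case the density is defective (it integrates to
#' \eqn{\exp(2 \cdot drift \cdot dist) < 1}, the probability that the
#' accumulator ever reaches the boundary).
#'
#' @param t decision time in seconds (strictly positive; vectorised).
#' @param drift mean evidence-accumulation rate (any real).
#' @param dist effective threshold distance (threshold minus start-point
#'   offset; strictly positive).
#' @param log logical; return the log-density.
#' @return density values (1/s), or log-densities.
#' @examples
#' dwald(1, drift = 1, dist = 1) # 1/sqrt(2*pi)
#' @export
dwald <- function(t, drift, dist, log = FALSE) {
  if (any(t <= 0)) stop("decision time `t` must be > 0")
  if (any(dist <= 0)) stop("threshold distance `dist` must be > 0")
  lp <- base::log(dist) - 0.5 * (base::log(2 * pi) + 3 * base::log(t)) -
    (dist - drift * t)^2 / (2 * t)
  if (log) lp else exp(lp)
}

#' Single-boundary diffusion first-passage-time distribution function
#'
#' Probability that the accumulator has reached its boundary by time `t`.
#' Extended to non-positive drifts, where the limit as \eqn{t \to \infty} is
#' the defective mass \eqn{\exp(2 \cdot drift \cdot dist)} rather than 1.
#' Computed in log space so that extreme `drift * dist` products do not
#' overflow.
#'
#' @inheritParams dwald
#' @param lower.tail if `FALSE`, return the survival probability
#'   \eqn{P(T > t)} (which includes the never-finishing mass for defective
#'   accumulators).
#' @param log.p logical; return log-probability.
#' @export
pwald <- function(t, drift, dist, lower.tail = TRUE, log.p = FALSE) {
  if (any(t <= 0)) stop("decision time `t` must be > 0")
  if (any(dist <= 0)) stop("threshold distance `dist` must be > 0")
  sq <- sqrt(t)
  ## F(t) = Phi((drift t - dist)/sqrt(t)) + e^{2 drift dist} Phi(-(drift t + dist)/sqrt(t))
  f1 <- pnorm((drift * t - dist) / sq, log.p = TRUE)
  f2 <- 2 * drift * dist + pnorm(-(drift * t + dist) / sq, log.p = TRUE)
  m <- pmax(f1, f2)
  logF <- m + log(exp(f1 - m) + exp(f2 - m))
  logF <- pmin(logF, 0)
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    ## survival: S = Phi((dist - drift t)/sqrt(t)) - e^{2 drift dist} Phi(-(dist + drift t)/sqrt(t))
    l1 <- pnorm((dist - drift * t) / sq, log.p = TRUE)
    l2 <- 2 * drift * dist + pnorm(-(dist + drift * t) / sq, log.p = TRUE)
    d <- l2 - l1
    logS <- ifelse(d >= 0, -Inf, l1 + log1p(-exp(d)))
    if (log.p) logS else exp(logS)
  }
}

#' Construct a set of racing accumulators
#'
#' One row per response option: a drift rate and a strictly positive effective
#' threshold distance (threshold `B` minus any start-point offset). Start-point
#' offsets are therefore expressed by reducing `dist`, which is mathematically
#' identical to moving the start point toward the boundary.
#'
#' @param drift numeric vector of drift rates.
#' @param dist numeric vector (or scalar) of effective threshold distances.
#' @return a matrix of class `accumulator_set` with columns `drift`, `dist`.
#' @export
accumulator_set <- function(drift, dist) {
  dist <- rep_len(dist, length(drift))
  if (any(!is.finite(drift))) stop("drift rates must be finite")
  if (any(!is.finite(dist)) || any(dist <= 0))
    stop("effective threshold distance must be finite and > 0")
  structure(cbind(drift = drift, dist = dist), class = "accumulator_set")
}

#' Log-likelihood of one observed race
#'
#' The racing diffusion likelihood of observing response `choice` at response
#' time `rt`: the winner's first-passage density at the decision time
#' `rt - t0` times every loser's survival probability at that time. Responses
#' at or before the non-decision time have zero likelihood and return `-Inf`
#' (not an error), so samplers can reject such parameter proposals gracefully.
#'
#' @param rt observed response time in seconds.
#' @param choice index of the winning accumulator (row of `accs`).
#' @param accs an [accumulator_set()] (or matrix with columns drift, dist).
#' @param t0 non-decision time in seconds (encoding + motor time).
#' @return the log-density (finite or `-Inf`).
#' @export
race_loglik <- function(rt, choice, accs, t0) {
  n_acc <- nrow(accs)
  if (length(choice) != 1 || choice < 1 || choice > n_acc)
    stop("`choice` must index a row of `accs`")
  dt <- rt - t0
  if (!is.finite(dt) || dt <= 0) return(-Inf)
  lp <- dwald(dt, accs[choice, "drift"], accs[choice, "dist"], log = TRUE)
  if (n_acc > 1) {
    losers <- setdiff(seq_len(n_acc), choice)
    ls <- pwald(dt, accs[losers, "drift"], accs[losers, "dist"],
                lower.tail = FALSE, log.p = TRUE)
    lp <- lp + sum(pmax(ls, -700)) # underflow floor on survival terms
  }
  unname(lp)
}

#' Sample first-passage times of single-boundary diffusion accumulators
#'
#' Exact draws (no time discretisation): for positive drift an inverse-Gaussian
#' draw by the Michael-Schucany-Haas transformation; for zero drift the Levy
#' first-passage law \eqn{dist^2 / Z^2}; for negative drift a Bernoulli hit
#' (probability \eqn{e^{2 drift \cdot dist}}) followed, on a hit, by an
#' inverse-Gaussian draw with the reflected drift. Misses return `Inf`.
#'
#' @param n number of draws.
#' @inheritParams dwald
#' @return numeric vector of first-passage times (possibly `Inf`).
#' @export
rwald <- function(n, drift, dist) {
  drift <- rep_len(drift, n)
  dist <- rep_len(dist, n)
  if (any(dist <= 0)) stop("threshold distance `dist` must be > 0")
  out <- rep(Inf, n)
  zero <- drift == 0
  if (any(zero)) out[zero] <- dist[zero]^2 / rnorm(sum(zero))^2
  hit <- !zero & (drift > 0 | runif(n) < exp(2 * drift * dist))
  m <- sum(hit)
  if (m) {
    mu <- dist[hit] / abs(drift[hit])
    lambda <- dist[hit]^2
    y <- rnorm(m)^2
    x <- mu + mu^2 * y / (2 * lambda) -
      mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
    u <- runif(m)
    out[hit] <- ifelse(u <= mu / (mu + x), x, mu^2 / x)
  }
  out
}

#' Simulate races between accumulators
#'
#' Draws one independent first-passage time per accumulator and returns the
#' winner (`choice`) and its time plus the non-decision time (`rt`). When no
#' accumulator has a positive drift the race may never finish; a finite
#' `horizon` must then be supplied, and races in which no accumulator finishes
#' within it are returned with `NA` choice and rt.
#'
#' @param accs an [accumulator_set()].
#' @param t0 non-decision time (s).
#' @param n number of races.
#' @param seed optional integer seed for reproducibility.
#' @param horizon optional finite guard horizon (s) for all-defective races.
#' @return data.frame with columns `choice` and `rt`.
#' @export
sample_race <- function(accs, t0, n = 1, seed = NULL, horizon = NULL) {
  if (all(accs[, "drift"] <= 0) && is.null(horizon))
    stop("no accumulator has positive drift; set a finite `horizon` to bound the race")
  with_seed(seed, {
    fpt <- vapply(seq_len(nrow(accs)),
                  function(i) rwald(n, accs[i, "drift"], accs[i, "dist"]),
                  numeric(n))
    fpt <- matrix(fpt, nrow = n)
    choice <- max.col(-fpt, ties.method = "first")
    rt <- fpt[cbind(seq_len(n), choice)] + t0
    if (!is.null(horizon)) {
      miss <- fpt[cbind(seq_len(n), choice)] > horizon
      choice[miss] <- NA_integer_
      rt[miss] <- NA_real_
    }
    data.frame(choice = choice, rt = rt)
  })
}

#' Choice probability of one accumulator winning the race, by quadrature
#'
#' Integrates the race density of the given choice over decision time with an
#' adaptive quadrature (absolute tolerance 1e-6), using an upper horizon at
#' which the total finishing probability exceeds 1 - 1e-8.
#'
#' @inheritParams race_loglik
#' @export
race_choice_prob <- function(choice, accs) {
  f <- function(t) {
    vapply(t, function(ti) {
      exp(race_loglik(ti, choice, accs, t0 = 0))
    }, numeric(1))
  }
  horizon <- race_horizon(accs)
  stats::integrate(f, 0, horizon, abs.tol = 1e-6,
                   subdivisions = 500L)$value
}

## Smallest t at which every accumulator has CDF mass within 1e-8 of its
## limit, found by doubling; used as the quadrature horizon.
race_horizon <- function(accs) {
  h <- 1
  repeat {
    done <- all(vapply(seq_len(nrow(accs)), function(i) {
      mu <- accs[i, "drift"]; a <- accs[i, "dist"]
      lim <- if (mu > 0) 1 else exp(2 * mu * a)
      lim - pwald(h, mu, a) < 1e-8
    }, logical(1)))
    if (done || h > 1e6) return(h)
    h <- h * 2
  }
}
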