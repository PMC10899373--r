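## Synthetic cohorts: group-level parameter structure (multivariate normal or
## factor-analytic), subject-level parameter draws on the unconstrained
## sampling scale, and full trial-level data simulated through the task models
## and the race simulator.

## Generating group medians on the natural scale (plausible adult values for
## these paradigms); used as the default group means of synthetic cohorts.
.default_medians <- list(
  rl_rev = c(alpha_learn = 0.18, V0 = 2.08, delta = 1.50, sigma_sum = 0.48,
             B = 1.63, t0 = 0.13),
  rl_sat = c(alpha_learn = 0.07, V0_spd = 3.06, V0_acc = 2.74, delta = 2.47,
             sigma_sum = 0.66, B_spd = 1.79, B_acc = 1.99, t0 = 0.12),
  rb = c(V0_tt1 = 1.97, V0_tt2 = 1.78, delta_r1t1 = 2.57, delta_r2t1 = 2.60,
         delta_r1t2 = 2.19, delta_r2t2 = 1.63, B_st1 = 1.68, B_st2 = 1.90,
         t0 = 0.12),
  msit = c(v_flank = 1.13, v_simon = 1.13, delta = 2.60, start_pos1 = 0.04,
           start_pos2 = 0.11, V0 = 0.68, B = 1.83, t0 = 0.21)
)

## Default between-subject SDs on the sampling scale, by transform kind.
.default_sds <- c(identity = 0.3, log = 0.2, logit = 0.5)

#' Concatenated parameter layout of a (joint) model
#'
#' Names, sampling-scale transforms and task slices of the per-subject
#' parameter vector for a set of tasks, optionally replicated over sessions
#' (between-session joint models estimate one parameter set per session;
#' between-task joint models pool sessions).
#'
#' @param tasks character vector of task ids.
#' @param sessions number of parameter replicates (1 = pooled).
#' @return list with `names`, `transforms`, and a data.frame `map` giving the
#'   task, session and base name of every entry.
#' @export
param_layout <- function(tasks, sessions = 1) {
  blocks <- list()
  for (s in seq_len(sessions)) {
    for (tk in tasks) {
      base <- task_param_names(tk)
      pre <- if (sessions > 1) paste0("s", s, ".", tk, ".") else
        if (length(tasks) > 1) paste0(tk, ".") else ""
      blocks[[length(blocks) + 1]] <- data.frame(
        name = paste0(pre, base), task = tk, session = s, base = base)
    }
  }
  map <- do.call(rbind, blocks)
  transforms <- unlist(lapply(seq_len(nrow(map)), function(i)
    task_transforms(map$task[i])[map$base[i]]))
  list(names = map$name, transforms = setNames(transforms, map$name),
       map = map)
}

#' Default sampling-scale group means for a parameter layout
#'
#' Natural-scale generating medians mapped through each parameter's transform.
#'
#' @param layout a [param_layout()].
#' @export
default_group_mu <- function(layout) {
  nat <- vapply(seq_along(layout$names), function(i)
    .default_medians[[layout$map$task[i]]][[layout$map$base[i]]], numeric(1))
  tr <- layout$transforms
  out <- nat
  out[tr == "log"] <- log(nat[tr == "log"])
  out[tr == "logit"] <- stats::qlogis(nat[tr == "logit"])
  setNames(out, layout$names)
}

default_group_sds <- function(layout) {
  setNames(.default_sds[layout$transforms], layout$names)
}

#' Specify a synthetic cohort
#'
#' The group level is either a full multivariate normal over the concatenated
#' sampling-scale parameter vector, or a factor structure
#' \eqn{\alpha_i = \mu + \Lambda \eta_i + e_i}. For two-session multivariate
#' cohorts, the two sessions' parameter vectors are drawn jointly with
#' per-parameter cross-session correlation `session_rho` (marginal covariance
#' `Sigma` in each session, cross-covariance `session_rho * Sigma`).
#'
#' @param n_subjects cohort size.
#' @param tasks task ids included.
#' @param sessions 1 or 2.
#' @param structure `"mvn"` or `"factor"`.
#' @param mu group mean on the sampling scale (default: transformed
#'   generating medians).
#' @param Sigma group covariance (mvn; default diagonal with the package's
#'   default between-subject SDs).
#' @param Lambda p x k loadings (factor).
#' @param eps length-p positive uniquenesses (factor).
#' @param session_rho cross-session correlation of matched parameters.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, tasks = "rl_rev", sessions = 1,
                        structure = c("mvn", "factor"),
                        mu = NULL, Sigma = NULL, Lambda = NULL, eps = NULL,
                        session_rho = 0.6) {
  structure <- match.arg(structure)
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  layout <- param_layout(tasks, sessions = if (structure == "mvn") 1 else 1)
  p <- length(layout$names)
  if (is.null(mu)) mu <- default_group_mu(layout)
  stopifnot(length(mu) == p)
  if (structure == "mvn") {
    if (is.null(Sigma)) Sigma <- diag(default_group_sds(layout)^2, p)
    stopifnot(nrow(Sigma) == p, isSymmetric(unname(Sigma)))
    if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("`Sigma` must be positive definite")
  } else {
    if (is.null(Lambda)) Lambda <- default_factor_loadings(layout)
    Lambda <- as.matrix(Lambda)
    stopifnot(nrow(Lambda) == p)
    if (is.null(eps)) {
      tot <- default_group_sds(layout)^2
      eps <- pmax(tot - rowSums(Lambda^2), 0.01)
    }
    stopifnot(length(eps) == p, all(eps > 0))
  }
  out <- list(n_subjects = n_subjects, tasks = tasks, sessions = sessions,
              structure = structure, layout = layout, mu = mu, Sigma = Sigma,
              Lambda = Lambda, eps = eps, session_rho = session_rho)
  class(out) <- "cohort_spec"
  out
}

#' Default two-factor generating loadings
#'
#' Emulates the qualitative structure the between-task analysis targets:
#' factor 1 loads on the information-processing (difference) parameters of
#' every task; factor 2 loads on the threshold and urgency parameters of the
#' learning tasks. The first parameter's loading on factor 2 is zero by the
#' ordering convention (reversal-learning parameters first), matching the
#' estimation constraint.
#'
#' @param layout a [param_layout()].
#' @param strength loading magnitude on the sampling scale.
#' @export
default_factor_loadings <- function(layout, strength = 0.25) {
  p <- length(layout$names)
  L <- matrix(0, p, 2)
  f1 <- grepl("delta", layout$map$base) | grepl("^v_", layout$map$base)
  f2 <- layout$map$task %in% c("rl_rev", "rl_sat") &
    (grepl("^B", layout$map$base) | grepl("^V0", layout$map$base))
  L[f1, 1] <- strength
  L[f2, 2] <- strength
  L[1, 2] <- 0
  L
}

#' Draw subject-level parameter vectors for a cohort
#'
#' Subjects are drawn on the unconstrained sampling scale (multivariate
#' normal, or the factor model's implied normal), then mapped to the natural
#' scale through the transform table, so positivity and range constraints hold
#' by construction.
#'
#' @param cohort a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `alpha` (n x p sampling scale; for two-session mvn
#'   cohorts n x 2p with session-prefixed names), `natural` (same shape,
#'   natural scale) and the generating `cohort`.
#' @export
gen_subjects <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  p <- length(cohort$mu)
  with_seed(seed, {
    if (cohort$structure == "mvn") {
      if (cohort$sessions == 2) {
        rho <- cohort$session_rho
        big_mu <- c(cohort$mu, cohort$mu)
        big_S <- rbind(cbind(cohort$Sigma, rho * cohort$Sigma),
                       cbind(rho * cohort$Sigma, cohort$Sigma))
        alpha <- MASS::mvrnorm(cohort$n_subjects, big_mu, make_pd(big_S, 1e-10))
        layout2 <- param_layout(cohort$tasks, sessions = 2)
        colnames(alpha) <- layout2$names
        transforms <- layout2$transforms
      } else {
        alpha <- MASS::mvrnorm(cohort$n_subjects, cohort$mu, cohort$Sigma)
        alpha <- matrix(alpha, ncol = p,
                        dimnames = list(NULL, cohort$layout$names))
        transforms <- cohort$layout$transforms
      }
    } else {
      k <- ncol(cohort$Lambda)
      eta <- matrix(rnorm(cohort$n_subjects * k), cohort$n_subjects, k)
      e <- matrix(rnorm(cohort$n_subjects * p), cohort$n_subjects, p) %*%
        diag(sqrt(cohort$eps), p)
      alpha <- sweep(eta %*% t(cohort$Lambda) + e, 2, cohort$mu, "+")
      colnames(alpha) <- cohort$layout$names
      transforms <- cohort$layout$transforms
    }
    natural <- to_natural(alpha, transforms)
    list(alpha = alpha, natural = natural, cohort = cohort)
  })
}

## Simulate one subject's trials on one task from natural-scale parameters
## (base names). Learning tasks thread the value state online: the simulated
## choice determines the realised feedback, which updates the values.
simulate_task_trials <- function(params, design, task, seed = NULL) {
  with_seed(seed, {
    n <- nrow(design)
    if (task %in% c("rl_rev", "rl_sat")) {
      choice <- integer(n); rt <- numeric(n); reward <- numeric(n)
      q <- c(Q0, Q0); blk <- -1L
      for (i in seq_len(n)) {
        if (design$block[i] != blk) { q <- c(Q0, Q0); blk <- design$block[i] }
        cond <- list(emphasis = if (task == "rl_sat") design$emphasis[i])
        accs <- rl_ard_accumulators(params, q, cond, task)
        race <- sample_race(accs, params["t0"], n = 1)
        choice[i] <- race$choice; rt[i] <- race$rt
        reward[i] <- if (race$choice == 1) design$reward1[i] else design$reward2[i]
        q <- update_q(q, race$choice, reward[i], params["alpha_learn"])
      }
      out <- cbind(design, choice = choice, rt_s = rt, reward = reward)
      out$correct <- as.integer((out$p1 >= out$p2) == (out$choice == 1))
      out$deadline_exceeded <- if (task == "rl_sat")
        as.integer(out$rt_s > out$deadline) else NA_integer_
      out
    } else if (task == "rb") {
      drift <- matrix(0, n, 2); dist <- numeric(n)
      for (i in seq_len(n)) {
        accs <- rb_accumulators(params, as.list(design[i, c(
          "trial_type", "correct_resp", "type_trans", "stim_trans")]))
        drift[i, ] <- accs[, "drift"]; dist[i] <- accs[1, "dist"]
      }
      fpt <- cbind(rwald(n, drift[, 1], dist), rwald(n, drift[, 2], dist))
      choice <- max.col(-fpt, ties.method = "first")
      rt <- fpt[cbind(seq_len(n), choice)] + params["t0"]
      out <- cbind(design, choice = choice, rt_s = rt)
      out$correct <- as.integer(out$choice == out$correct_resp)
      out
    } else {
      drift <- matrix(0, n, 3); dist <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        accs <- msit_accumulators(params, as.list(design[i, c(
          "target", "position", "flanker", "simon")]))
        drift[i, ] <- accs[, "drift"]; dist[i, ] <- accs[, "dist"]
      }
      fpt <- vapply(1:3, function(k) rwald(n, drift[, k], dist[, k]),
                    numeric(n))
      choice <- max.col(-fpt, ties.method = "first")
      rt <- fpt[cbind(seq_len(n), choice)] + params["t0"]
      out <- cbind(design, choice = choice, rt_s = rt)
      out$correct <- as.integer(out$choice == out$target)
      out
    }
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws subject parameters from the cohort's group structure, generates a
#' fresh design realisation per subject/task/session, and simulates every
#' trial through the task models and the race simulator. The master seed
#' deterministically spawns per-subject/task/session child seeds, so any slice
#' of the cohort is reproducible on its own. Responses slower than a deadline
#' (speed-accuracy task) are flagged, not censored.
#'
#' @param cohort a [cohort_spec()].
#' @param designs named list of [design_spec()]s, one per task (defaults used
#'   for tasks not listed).
#' @param seed master integer seed.
#' @return data.frame of trials; attributes `truth` (the generating subject
#'   parameters and cohort spec) and `seed`.
#' @export
simulate_cohort <- function(cohort, designs = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  designs <- designs %||% list()
  for (tk in cohort$tasks)
    if (is.null(designs[[tk]])) designs[[tk]] <- design_spec(tk)
  subj <- gen_subjects(cohort, seed = spawn_seed(seed, 0))
  rows <- list()
  idx <- 1L
  for (s in seq_len(nrow(subj$natural))) {
    for (sess in seq_len(cohort$sessions)) {
      for (tk in cohort$tasks) {
        prefix <- if (cohort$structure == "mvn" && cohort$sessions == 2)
          paste0("s", sess, ".", tk, ".") else
          if (length(cohort$tasks) > 1) paste0(tk, ".") else ""
        nm <- paste0(prefix, task_param_names(tk))
        params <- setNames(subj$natural[s, nm], task_param_names(tk))
        child <- spawn_seed(seed, idx); idx <- idx + 1L
        des <- gen_design(designs[[tk]], seed = child)
        tr <- simulate_task_trials(params, des, tk,
                                   seed = spawn_seed(child, 1))
        tr$subject <- s; tr$task <- tk; tr$session <- sess
        rows[[length(rows) + 1L]] <- tr
      }
    }
  }
  ## align all column sets
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  front <- c("subject", "task", "session", "block", "trial")
  out <- out[c(front, setdiff(cols, front))]
  out <- out[order(out$subject, out$task, out$session, out$block, out$trial), ]
  rownames(out) <- NULL
  attr(out, "truth") <- subj
  attr(out, "seed") <- seed
  out
}

#' Write a cohort to disk (trial CSV plus ground-truth JSON sidecar)
#'
#' @param trials output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "trials.csv")
  utils::write.csv(trials, csv, row.names = FALSE)
  truth <- attr(trials, "truth")
  side <- file.path(dir, "truth.json")
  cj <- truth$cohort
  jsonlite::write_json(list(
    seed = attr(trials, "seed"),
    n_subjects = cj$n_subjects, tasks = cj$tasks, sessions = cj$sessions,
    structure = cj$structure, mu = as.list(setNames(cj$mu, cj$layout$names)),
    Sigma = cj$Sigma, Lambda = cj$Lambda, eps = cj$eps,
    session_rho = cj$session_rho,
    alpha = truth$alpha), side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, side))
}
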