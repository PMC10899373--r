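## Task-specific racing diffusion models: parameter vocabularies, drift-rate
## construction from trial condition codes, and the delta-rule value dynamics
## for the learning tasks.

TASKS <- c("rl_rev", "rl_sat", "rb", "msit")

## Canonical (reported) parameter order. The reversal-learning task leads with
## its difference parameter so that, in the concatenated between-task vector,
## the first row of the factor-loading matrix is that task's delta -- the row
## whose above-diagonal loading is pinned to zero by the identification
## constraint.
.task_params <- list(
  rl_rev = c("delta", "B", "t0", "V0", "alpha_learn", "sigma_sum"),
  rl_sat = c("alpha_learn", "V0_spd", "V0_acc", "delta", "sigma_sum",
             "B_spd", "B_acc", "t0"),
  rb     = c("V0_tt1", "V0_tt2", "delta_r1t1", "delta_r2t1", "delta_r1t2",
             "delta_r2t2", "B_st1", "B_st2", "t0"),
  msit   = c("v_flank", "v_simon", "delta", "start_pos1", "start_pos2",
             "V0", "B", "t0")
)

## Column order expected by the compiled likelihood kernels.
.cpp_params <- list(
  rl_rev = c("alpha_learn", "V0", "delta", "sigma_sum", "B", "t0"),
  rl_sat = .task_params$rl_sat,
  rb = .task_params$rb,
  msit = .task_params$msit
)

#' Parameter names of a task-specific racing diffusion model
#'
#' The four models have 6 (`rl_rev`), 8 (`rl_sat`), 9 (`rb`) and 8 (`msit`)
#' free parameters; their concatenation across all four tasks is the
#' 31-dimensional per-subject vector of the between-task joint model.
#'
#' @param task one of `"rl_rev"`, `"rl_sat"`, `"rb"`, `"msit"`.
#' @return character vector of parameter names (natural scale).
#' @export
task_param_names <- function(task) {
  task <- match.arg(task, TASKS)
  .task_params[[task]]
}

#' Sampling-scale transforms of a task's parameters
#'
#' Hierarchical estimation happens on an unconstrained scale: thresholds and
#' non-decision times are log-transformed, learning rates logit-transformed,
#' and drift-type parameters (urgency, difference, sum weights, interference
#' supports, start-point modifiers) are left on the natural scale.
#'
#' @inheritParams task_param_names
#' @return named character vector with values `"log"`, `"logit"`, `"identity"`.
#' @export
task_transforms <- function(task) {
  nm <- task_param_names(task)
  tr <- rep("identity", length(nm))
  tr[grepl("^B", nm) | nm == "t0"] <- "log"
  tr[nm == "alpha_learn"] <- "logit"
  setNames(tr, nm)
}

## Map a matrix/vector of sampling-scale values to the natural scale given a
## transform vector, and back.
to_natural <- function(x, transforms) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  out <- x
  lg <- transforms == "log"; lt <- transforms == "logit"
  out[, lg] <- exp(x[, lg, drop = FALSE])
  out[, lt] <- stats::plogis(x[, lt, drop = FALSE])
  out
}

to_sampling <- function(x, transforms) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  out <- x
  lg <- transforms == "log"; lt <- transforms == "logit"
  out[, lg] <- log(x[, lg, drop = FALSE])
  out[, lt] <- stats::qlogis(x[, lt, drop = FALSE])
  out
}

#' Delta-rule update of expected values
#'
#' `Q <- Q + alpha_learn * (r - Q)` for the chosen stimulus only; the input
#' state is not modified.
#'
#' @param q named numeric vector of expected values, one per stimulus.
#' @param chosen name (or index) of the chosen stimulus.
#' @param r realised reward.
#' @param alpha_learn learning rate in (0, 1].
#' @return the updated value vector.
#' @export
update_q <- function(q, chosen, r, alpha_learn) {
  if (alpha_learn <= 0 || alpha_learn > 1)
    stop("`alpha_learn` must lie in (0, 1]")
  if (is.character(chosen) && !chosen %in% names(q))
    stop("unknown stimulus: ", chosen)
  if (is.numeric(chosen) && (chosen < 1 || chosen > length(q)))
    stop("unknown stimulus index: ", chosen)
  q[chosen] <- q[chosen] + alpha_learn * (r - q[chosen])
  q
}

check_params <- function(params, task) {
  nm <- task_param_names(task)
  if (!all(nm %in% names(params)))
    stop("missing ", task, " parameters: ",
         paste(setdiff(nm, names(params)), collapse = ", "))
  params[nm]
}

#' Advantage-framework accumulators for the learning tasks
#'
#' Drift of each option is urgency plus a weighted value difference plus a
#' weighted value sum:
#' `v_i = V0 + delta * (Q_i - Q_j) + sigma_sum * (Q_i + Q_j)`.
#' For the speed-accuracy task, urgency and threshold are selected by the
#' trial's emphasis cue (`"spd"` or `"acc"`); learning rate, difference and
#' sum weights and non-decision time are shared across emphasis.
#'
#' @param params named parameter vector (natural scale) for `rl_rev` or
#'   `rl_sat`.
#' @param q numeric length-2 vector of the pair's current expected values.
#' @param cond list of condition codes; for `rl_sat` must contain
#'   `emphasis` in `c("spd", "acc")`.
#' @param task `"rl_rev"` or `"rl_sat"`.
#' @return an [accumulator_set()] with two rows.
#' @export
rl_ard_accumulators <- function(params, q, cond = list(), task = "rl_rev") {
  task <- match.arg(task, c("rl_rev", "rl_sat"))
  params <- check_params(params, task)
  if (task == "rl_rev") {
    v0 <- params["V0"]; b <- params["B"]
  } else {
    emph <- cond$emphasis
    if (is.null(emph) || !emph %in% c("spd", "acc"))
      stop("rl_sat trials require an emphasis code 'spd' or 'acc'")
    v0 <- params[paste0("V0_", emph)]
    b <- params[paste0("B_", emph)]
  }
  d <- params["delta"] * c(q[1] - q[2], q[2] - q[1])
  s <- params["sigma_sum"] * sum(q)
  accumulator_set(drift = unname(v0 + d + s), dist = unname(b))
}

#' Reference-back accumulators
#'
#' Sensitivity parameterisation: the correct response's accumulator gets
#' `V0 + delta`, the error accumulator `V0 - delta`, where the urgency `V0`
#' depends on the trial-type transition (repeat/switch) and `delta` on the
#' crossing of trial type (reference/comparison) with the correct response
#' (same/different). The threshold depends on the stimulus-identity
#' transition.
#'
#' @param params named `rb` parameter vector (natural scale).
#' @param cond list with integer codes `trial_type` (1 or 2),
#'   `correct_resp` (1 = same, 2 = different), `type_trans` (1 = repeat,
#'   2 = switch), `stim_trans` (1 = repeat, 2 = switch).
#' @return an [accumulator_set()] with rows ordered by response (1 = same,
#'   2 = different).
#' @export
rb_accumulators <- function(params, cond) {
  params <- check_params(params, "rb")
  for (f in c("trial_type", "correct_resp", "type_trans", "stim_trans")) {
    v <- cond[[f]]
    if (is.null(v) || !v %in% 1:2)
      stop("rb condition field `", f, "` must be 1 or 2")
  }
  v0 <- params[paste0("V0_tt", cond$type_trans)]
  dl <- params[paste0("delta_r", cond$correct_resp, "t", cond$trial_type)]
  b <- params[paste0("B_st", cond$stim_trans)]
  drift <- rep(unname(v0 - dl), 2)
  drift[cond$correct_resp] <- unname(v0 + dl)
  accumulator_set(drift = drift, dist = unname(b))
}

#' Multi-source interference task accumulators
#'
#' Three response accumulators. Each drift is the urgency plus the sum of the
#' evidence supporting that response: flanker support `v_flank` if the flanker
#' digit matches, Simon support `v_simon` if the spatial position primes that
#' response, and target support `delta` for the correct response. The target
#' accumulator's start point is moved toward the boundary by a
#' position-dependent modifier (`start_pos3` is fixed at 0 as the reference
#' position), implemented as a reduction of its threshold distance.
#'
#' @param params named `msit` parameter vector (natural scale).
#' @param cond list with `target` (1:3), `position` (1:3), `flanker`
#'   (0 = none, else the flanking digit 1:3) and `simon` (0 = none, else the
#'   response primed by the target position).
#' @return an [accumulator_set()] with three rows.
#' @export
msit_accumulators <- function(params, cond) {
  params <- check_params(params, "msit")
  if (!cond$target %in% 1:3 || !cond$position %in% 1:3)
    stop("msit target identity and position must be in 1:3")
  if (!cond$flanker %in% 0:3 || !cond$simon %in% 0:3)
    stop("msit flanker/simon codes must be 0 (absent) or a response in 1:3")
  start_pos <- c(params["start_pos1"], params["start_pos2"], 0)
  drift <- rep(unname(params["V0"]), 3)
  if (cond$flanker > 0) drift[cond$flanker] <- drift[cond$flanker] + params["v_flank"]
  if (cond$simon > 0) drift[cond$simon] <- drift[cond$simon] + params["v_simon"]
  drift[cond$target] <- drift[cond$target] + params["delta"]
  dist <- rep(unname(params["B"]), 3)
  dist[cond$target] <- dist[cond$target] - unname(start_pos[cond$position])
  if (any(dist <= 0))
    stop("start-point modifier exceeds threshold: nonpositive effective distance")
  accumulator_set(drift = drift, dist = dist)
}

## Initial expected value at block start (rewards are on a 0-1 scale).
Q0 <- 0.5

#' Log-likelihood of one subject's trials under a task model
#'
#' Reference implementation in plain R: threads the delta-rule value state
#' through the learning-task trials (reset to the initial value at every block
#' start), builds the per-trial accumulator sets, and sums the race
#' log-likelihoods. Trials must be ordered by block and trial index. Parameter
#' vectors for which some trial has zero likelihood (for example `rt <= t0`)
#' give `-Inf`.
#'
#' For use inside samplers, [task_loglik()] evaluates the same function for
#' many parameter vectors at once in compiled code; equality of the two paths
#' is part of the test suite.
#'
#' @param params named natural-scale parameter vector.
#' @param trials data.frame of one subject's trials for one task (columns as
#'   produced by [simulate_cohort()]).
#' @param task the task id.
#' @return scalar log-likelihood (finite or `-Inf`).
#' @export
dataset_loglik <- function(params, trials, task) {
  task <- match.arg(task, TASKS)
  if (nrow(trials) == 0) return(0)
  if (!is.null(trials$block)) {
    o <- order(trials$block, trials$trial)
    if (any(o != seq_len(nrow(trials))))
      stop("trials must be sorted by block and trial index")
  }
  params <- check_params(params, task)
  ll <- 0
  if (task %in% c("rl_rev", "rl_sat")) {
    t0 <- params["t0"]
    q <- c(Q0, Q0)
    blk <- -1L
    for (i in seq_len(nrow(trials))) {
      if (trials$block[i] != blk) {
        q <- c(Q0, Q0)
        blk <- trials$block[i]
      }
      cond <- list(emphasis = if (task == "rl_sat") trials$emphasis[i])
      accs <- rl_ard_accumulators(params, q, cond, task)
      ll <- ll + race_loglik(trials$rt_s[i], trials$choice[i], accs, t0)
      if (!is.finite(ll)) return(-Inf)
      q <- update_q(q, trials$choice[i], trials$reward[i],
                    params["alpha_learn"])
    }
  } else if (task == "rb") {
    for (i in seq_len(nrow(trials))) {
      accs <- rb_accumulators(params, as.list(trials[i, c(
        "trial_type", "correct_resp", "type_trans", "stim_trans")]))
      ll <- ll + race_loglik(trials$rt_s[i], trials$choice[i], accs,
                             params["t0"])
      if (!is.finite(ll)) return(-Inf)
    }
  } else {
    for (i in seq_len(nrow(trials))) {
      accs <- try(msit_accumulators(params, as.list(trials[i, c(
        "target", "position", "flanker", "simon")])), silent = TRUE)
      if (inherits(accs, "try-error")) return(-Inf)
      ll <- ll + race_loglik(trials$rt_s[i], trials$choice[i], accs,
                             params["t0"])
      if (!is.finite(ll)) return(-Inf)
    }
  }
  unname(ll)
}

#' Encode a task's trials for the vectorised likelihood
#'
#' Packs the condition codes, choices and response times of one subject's
#' trials into a numeric matrix consumed by the compiled likelihood kernel.
#'
#' @inheritParams dataset_loglik
#' @return numeric matrix with an attribute `task`.
#' @export
encode_trials <- function(trials, task) {
  task <- match.arg(task, TASKS)
  m <- switch(task,
    rl_rev = ,
    rl_sat = cbind(block = trials$block, choice = trials$choice,
                   reward = trials$reward,
                   emphasis = if (task == "rl_sat")
                     match(trials$emphasis, c("spd", "acc")) else 0,
                   rt = trials$rt_s),
    rb = cbind(trial_type = trials$trial_type,
               correct_resp = trials$correct_resp,
               type_trans = trials$type_trans,
               stim_trans = trials$stim_trans,
               choice = trials$choice, rt = trials$rt_s),
    msit = cbind(target = trials$target, position = trials$position,
                 flanker = trials$flanker, simon = trials$simon,
                 choice = trials$choice, rt = trials$rt_s))
  m <- matrix(as.numeric(m), nrow = nrow(trials),
              dimnames = list(NULL, colnames(m)))
  attr(m, "task") <- task
  m
}

#' Vectorised task log-likelihood over many parameter vectors
#'
#' Evaluates [dataset_loglik()] for every row of a natural-scale parameter
#' matrix in compiled code. Invalid parameter rows (nonpositive thresholds or
#' effective distances, learning rates outside (0,1), responses at or before
#' `t0`) give `-Inf`.
#'
#' @param params_nat numeric matrix, one parameter vector per row, columns in
#'   [task_param_names()] order.
#' @param enc encoded trials from [encode_trials()].
#' @return numeric vector of log-likelihoods, one per parameter row.
#' @export
task_loglik <- function(params_nat, enc) {
  task <- attr(enc, "task")
  if (is.null(dim(params_nat)))
    params_nat <- matrix(params_nat, nrow = 1,
                         dimnames = list(NULL, names(params_nat)))
  nm <- .cpp_params[[task]]
  if (is.null(colnames(params_nat))) colnames(params_nat) <- .task_params[[task]]
  params_nat <- params_nat[, nm, drop = FALSE]
  switch(task,
    rl_rev = cpp_loglik_rl(params_nat, enc, FALSE, Q0),
    rl_sat = cpp_loglik_rl(params_nat, enc, TRUE, Q0),
    rb = cpp_loglik_rb(params_nat, enc),
    msit = cpp_loglik_msit(params_nat, enc))
}
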