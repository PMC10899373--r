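## Synthetic task designs: trial sequences of condition codes with the
## structure each task's model assumes (reward reversals, emphasis schedules,
## transition bookkeeping, balanced interference conditions).

#' Specify a synthetic task design
#'
#' Defaults are a desk-scale session: reversal learning in blocks with the
#' reward contingencies of a pair swapped mid-block; speed/accuracy learning
#' with alternating emphasis mini-blocks and per-emphasis response deadlines;
#' a reference-back sequence with reference/comparison trials and tracked
#' trial-type and stimulus-identity transitions; and a factorial multi-source
#' interference design crossing interference type (neutral, flanker-only,
#' simon-only, combined) with target position.
#'
#' @param task task id.
#' @param blocks number of blocks (learning tasks).
#' @param trials_per_block trials in each block (learning tasks).
#' @param p_reward length-2 reward probabilities of the pair (better, worse).
#' @param reversal_trial trial within a block after which the pair's reward
#'   probabilities are swapped (`rl_rev` only).
#' @param miniblock run length of each emphasis regime (`rl_sat` only).
#' @param deadlines named response deadlines in seconds (`rl_sat` only).
#' @param n_trials total trials (`rb`, `msit`).
#' @param p_reference probability that an `rb` trial is a reference trial.
#' @return a list of class `design_spec`.
#' @export
design_spec <- function(task,
                        blocks = 4, trials_per_block = 60,
                        p_reward = c(0.8, 0.2), reversal_trial = 30,
                        miniblock = 12,
                        deadlines = c(spd = 0.7, acc = 1.5),
                        n_trials = if (task == "msit") 120 else 200,
                        p_reference = 0.5) {
  task <- match.arg(task, TASKS)
  stopifnot(blocks >= 1, trials_per_block >= 1, n_trials >= 1,
            all(p_reward >= 0 & p_reward <= 1),
            reversal_trial >= 1, reversal_trial < trials_per_block)
  structure(list(task = task, blocks = blocks,
                 trials_per_block = trials_per_block, p_reward = p_reward,
                 reversal_trial = reversal_trial, miniblock = miniblock,
                 deadlines = deadlines, n_trials = n_trials,
                 p_reference = p_reference),
            class = "design_spec")
}

#' Generate an ordered synthetic trial sequence
#'
#' Produces the per-trial condition codes (and, for the learning tasks, the
#' realised Bernoulli reward of each stimulus) of one run of the design.
#' Reproducible under a fixed seed.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed.
#' @return data.frame of condition codes, one row per trial.
#' @export
gen_design <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(seed, switch(spec$task,
    rl_rev = gen_design_rl(spec, reversal = TRUE),
    rl_sat = gen_design_rl(spec, reversal = FALSE),
    rb = gen_design_rb(spec),
    msit = gen_design_msit(spec)))
}

gen_design_rl <- function(spec, reversal) {
  out <- do.call(rbind, lapply(seq_len(spec$blocks), function(b) {
    n <- spec$trials_per_block
    p1 <- rep(spec$p_reward[1], n)
    p2 <- rep(spec$p_reward[2], n)
    if (reversal) {
      post <- seq_len(n) > spec$reversal_trial
      p1[post] <- spec$p_reward[2]
      p2[post] <- spec$p_reward[1]
    }
    emphasis <- NA_character_
    if (!reversal) {
      runs <- rep(c("spd", "acc"), length.out = ceiling(n / spec$miniblock))
      if (b %% 2 == 0) runs <- rev(runs)
      emphasis <- rep(runs, each = spec$miniblock)[seq_len(n)]
    }
    data.frame(block = b, trial = seq_len(n), p1 = p1, p2 = p2,
               reward1 = as.integer(runif(n) < p1),
               reward2 = as.integer(runif(n) < p2),
               emphasis = emphasis)
  }))
  out$deadline <- if (!reversal)
    unname(spec$deadlines[out$emphasis]) else NA_real_
  rownames(out) <- NULL
  out
}

gen_design_rb <- function(spec) {
  n <- spec$n_trials
  ref <- runif(n) < spec$p_reference
  ref[1] <- TRUE # the sequence must open with a reference to set the memory
  stim <- sample(1:2, n, replace = TRUE)
  reference <- integer(n)
  cur <- stim[1]
  for (i in seq_len(n)) {
    reference[i] <- cur
    if (ref[i]) cur <- stim[i] # reference trials update the memorised item
  }
  trial_type <- ifelse(ref, 1L, 2L) # 1 reference, 2 comparison
  correct_resp <- ifelse(stim == reference, 1L, 2L) # 1 same, 2 different
  type_trans <- c(1L, ifelse(trial_type[-1] == trial_type[-n], 1L, 2L))
  stim_trans <- c(1L, ifelse(stim[-1] == stim[-n], 1L, 2L))
  data.frame(block = 1L, trial = seq_len(n), trial_type = trial_type,
             correct_resp = correct_resp, type_trans = type_trans,
             stim_trans = stim_trans, stim = stim)
}

gen_design_msit <- function(spec) {
  types <- c("neutral", "flanker", "simon", "both")
  grid <- expand.grid(type = types, position = 1:3,
                      stringsAsFactors = FALSE)
  reps <- ceiling(spec$n_trials / nrow(grid))
  cells <- grid[rep(seq_len(nrow(grid)), reps)[seq_len(spec$n_trials)], ]
  cells <- cells[sample.int(nrow(cells)), ]
  n <- nrow(cells)
  target <- integer(n); flanker <- integer(n); simon <- integer(n)
  for (i in seq_len(n)) {
    pos <- cells$position[i]; ty <- cells$type[i]
    if (ty %in% c("neutral", "flanker")) {
      target[i] <- pos # target in its congruent position
    } else {
      target[i] <- sample(setdiff(1:3, pos), 1) # spatial conflict
    }
    flanker[i] <- if (ty %in% c("flanker", "both"))
      sample(setdiff(1:3, target[i]), 1) else 0L
    simon[i] <- if (ty %in% c("simon", "both")) pos else 0L
  }
  data.frame(block = 1L, trial = seq_len(n), type = cells$type,
             target = target, position = cells$position,
             flanker = flanker, simon = simon, row.names = NULL)
}
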