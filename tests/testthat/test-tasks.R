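# Task models: parameter vocabularies, drift construction, value dynamics,
# and the dataset likelihood (plain-R reference vs compiled fast path).

test_that("the four task models expose the reported parameter counts", {
  counts <- vapply(c("rl_rev", "rl_sat", "rb", "msit"),
                   function(t) length(task_param_names(t)), integer(1))
  expect_equal(unname(counts), c(6L, 8L, 9L, 8L))
  expect_equal(sum(counts), 31L) # concatenated between-task vector
  lay <- param_layout(c("rl_rev", "rl_sat", "rb", "msit"))
  expect_equal(length(lay$names), 31L)
  expect_false(any(duplicated(lay$names)))
})

test_that("delta-rule updates only the chosen stimulus and converges geometrically", {
  q <- c(a = 0.5, b = 0.2)
  q2 <- update_q(q, "a", r = 1, alpha_learn = 0.2)
  expect_equal(unname(q2), c(0.6, 0.2))
  expect_equal(update_q(q, "a", r = 0.5, alpha_learn = 0.3)[["a"]], 0.5)
  expect_equal(update_q(q, "b", r = 1, alpha_learn = 1)[["b"]], 1)
  expect_error(update_q(q, "c", 1, 0.2), "unknown stimulus")
  expect_error(update_q(q, "a", 1, 1.5), "alpha_learn")
  # |Q - r| shrinks as (1 - alpha)^n under constant reward
  al <- 0.3
  qq <- c(x = 0)
  for (n in 1:12) {
    qq <- update_q(qq, "x", r = 1, alpha_learn = al)
    expect_equal(abs(qq[["x"]] - 1), (1 - al)^n, tolerance = 1e-12)
  }
})

test_that("advantage-framework drifts combine urgency, difference and sum terms", {
  pars <- c(delta = 1.5, B = 1, t0 = 0.2, V0 = 2, alpha_learn = 0.1,
            sigma_sum = 0.5)
  accs <- rl_ard_accumulators(pars, q = c(0.8, 0.2))
  expect_equal(accs[, "drift"], c(3.4, 1.6)) # 2 + 1.5*.6 + .5*1; 2 - .9 + .5
  # equal values: difference term vanishes
  eq <- rl_ard_accumulators(pars, q = c(0.4, 0.4))
  expect_equal(eq[, "drift"], rep(2 + 2 * 0.5 * 0.4, 2))
  # swapping values swaps drifts
  sw <- rl_ard_accumulators(pars, q = c(0.2, 0.8))
  expect_equal(sw[, "drift"], rev(accs[, "drift"]))
  # emphasis selects urgency and threshold in the speed-accuracy variant
  sat <- c(alpha_learn = 0.1, V0_spd = 3, V0_acc = 2, delta = 1, sigma_sum = 0,
           B_spd = 0.8, B_acc = 1.6, t0 = 0.2)
  spd <- rl_ard_accumulators(sat, c(0.5, 0.5), list(emphasis = "spd"), "rl_sat")
  acc <- rl_ard_accumulators(sat, c(0.5, 0.5), list(emphasis = "acc"), "rl_sat")
  expect_equal(unname(spd[1, ]), c(3, 0.8))
  expect_equal(unname(acc[1, ]), c(2, 1.6))
  expect_error(rl_ard_accumulators(sat, c(0.5, 0.5), list(), "rl_sat"),
               "emphasis")
})

test_that("reference-back drifts follow the sensitivity parameterisation", {
  pars <- c(V0_tt1 = 2, V0_tt2 = 1.5, delta_r1t1 = 1.5, delta_r2t1 = 1,
            delta_r1t2 = 0.8, delta_r2t2 = 0.6, B_st1 = 1.2, B_st2 = 1.5,
            t0 = 0.15)
  cond <- list(trial_type = 1, correct_resp = 1, type_trans = 1, stim_trans = 1)
  accs <- rb_accumulators(pars, cond)
  expect_equal(accs[, "drift"], c(3.5, 0.5)) # V0 + delta, V0 - delta
  expect_equal(accs[, "dist"], rep(1.2, 2))
  # drifts always sum to twice the urgency
  for (tt in 1:2) for (cr in 1:2) for (tr in 1:2) {
    a <- rb_accumulators(pars, list(trial_type = tt, correct_resp = cr,
                                    type_trans = tr, stim_trans = 1))
    expect_equal(sum(a[, "drift"]), 2 * unname(pars[paste0("V0_tt", tr)]))
  }
  # zero sensitivity: chance-level discrimination
  p0 <- pars
  p0[paste0("delta_r", 1:2, "t1")] <- 0
  a0 <- rb_accumulators(p0, cond)
  expect_equal(a0[1, "drift"], a0[2, "drift"])
  expect_error(rb_accumulators(pars, list(trial_type = 3, correct_resp = 1,
                                          type_trans = 1, stim_trans = 1)),
               "must be 1 or 2")
})

test_that("interference drifts add flanker, simon and target support with positional start points", {
  pars <- c(v_flank = 1.2, v_simon = 0.9, delta = 2.8, start_pos1 = 0.05,
            start_pos2 = 0.1, V0 = 1, B = 1.8, t0 = 0.2)
  # neutral trial, target 2 at reference position 3: only target support
  neu <- msit_accumulators(pars, list(target = 2, position = 3,
                                      flanker = 0, simon = 0))
  expect_equal(neu[, "drift"], c(1, 3.8, 1))
  expect_equal(neu[, "dist"], rep(1.8, 3))
  # flanker digit 3 with spatial conflict at position 1
  con <- msit_accumulators(pars, list(target = 1, position = 1,
                                      flanker = 3, simon = 0))
  expect_equal(con[, "drift"], c(3.8, 1, 2.2))
  expect_equal(con[, "dist"], c(1.75, 1.8, 1.8))
  # congruent support: all three effects stack on the target
  all3 <- msit_accumulators(pars, list(target = 2, position = 2,
                                       flanker = 2, simon = 2))
  expect_equal(unname(all3[2, "drift"]), 1 + 1.2 + 0.9 + 2.8)
  # nonpositive effective distance is an error
  bad <- pars
  bad["start_pos1"] <- 2
  expect_error(msit_accumulators(bad, list(target = 1, position = 1,
                                           flanker = 0, simon = 0)),
               "effective distance")
})

test_that("dataset log-likelihood composes race terms and matches the compiled path", {
  expect_equal(dataset_loglik(c(delta = 1, B = 1, t0 = 0.2, V0 = 2,
                                alpha_learn = 0.2, sigma_sum = 0),
                              data.frame()[0, ], "rl_rev"), 0)
  set.seed(31)
  for (tk in c("rl_rev", "rl_sat", "rb", "msit")) {
    co <- cohort_spec(2, tasks = tk)
    des <- list(design_spec(tk, blocks = 1, trials_per_block = 30,
                            reversal_trial = 15, n_trials = 30))
    names(des) <- tk
    tr <- simulate_cohort(co, des, seed = 5)
    truth <- attr(tr, "truth")
    s1 <- tr[tr$subject == 1, ]
    enc <- encode_trials(s1, tk)
    # R reference path vs compiled path, at truth and at random perturbations
    for (j in 1:4) {
      pn <- truth$natural[1, ]
      names(pn) <- colnames(truth$natural)
      if (j > 1) {
        bump <- exp(rnorm(length(pn), 0, 0.1))
        pn <- pn * bump
        pn["alpha_learn"] <- min(pn["alpha_learn"], 0.95)
      }
      llR <- dataset_loglik(pn, s1, tk)
      llC <- task_loglik(matrix(pn, 1, dimnames = list(NULL, names(pn))), enc)
      expect_equal(llR, llC, tolerance = 1e-10)
    }
  }
  # single reference-back trial equals the race likelihood directly
  pars <- c(V0_tt1 = 2, V0_tt2 = 1.5, delta_r1t1 = 1.5, delta_r2t1 = 1,
            delta_r1t2 = 0.8, delta_r2t2 = 0.6, B_st1 = 1.2, B_st2 = 1.5,
            t0 = 0.15)
  one <- data.frame(block = 1, trial = 1, trial_type = 1, correct_resp = 1,
                    type_trans = 2, stim_trans = 2, choice = 2, rt_s = 0.8)
  expect_equal(dataset_loglik(pars, one, "rb"),
               race_loglik(0.8, 2, rb_accumulators(pars, as.list(one)), 0.15))
})

test_that("likelihood is higher at generating than at perturbed parameters", {
  # dominance over seeded replicates, reversal-learning task
  set.seed(77)
  wins <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    co <- cohort_spec(1, tasks = "rl_rev")
    tr <- simulate_cohort(co, list(rl_rev = design_spec(
      "rl_rev", blocks = 2, trials_per_block = 50)), seed = 100 + r)
    truth <- attr(tr, "truth")
    pn <- truth$natural[1, ]
    names(pn) <- colnames(truth$natural)
    pp <- pn
    pp["delta"] <- pp["delta"] + 1
    wins <- wins + (dataset_loglik(pn, tr, "rl_rev") >
                      dataset_loglik(pp, tr, "rl_rev"))
  }
  expect_gte(wins / reps, 0.9)
})

test_that("relabeling symmetries leave the likelihood unchanged", {
  # reference-back: swapping response labels and the matching deltas
  pars <- c(V0_tt1 = 2, V0_tt2 = 1.5, delta_r1t1 = 1.5, delta_r2t1 = 1,
            delta_r1t2 = 0.8, delta_r2t2 = 0.6, B_st1 = 1.2, B_st2 = 1.5,
            t0 = 0.15)
  sw <- pars
  sw[c("delta_r1t1", "delta_r2t1")] <- pars[c("delta_r2t1", "delta_r1t1")]
  sw[c("delta_r1t2", "delta_r2t2")] <- pars[c("delta_r2t2", "delta_r1t2")]
  co <- cohort_spec(1, tasks = "rb")
  tr <- simulate_cohort(co, list(rb = design_spec("rb", n_trials = 60)),
                        seed = 8)
  tr2 <- tr
  tr2$correct_resp <- 3L - tr$correct_resp
  tr2$choice <- 3L - tr$choice
  expect_equal(dataset_loglik(pars, tr, "rb"), dataset_loglik(sw, tr2, "rb"))
  # interference task: consistent permutation of response labels
  mp <- c(v_flank = 1.2, v_simon = 0.9, delta = 2.8, start_pos1 = 0,
          start_pos2 = 0, V0 = 1, B = 1.8, t0 = 0.2)
  com <- cohort_spec(1, tasks = "msit")
  trm <- simulate_cohort(com, list(msit = design_spec("msit", n_trials = 48)),
                         seed = 9)
  perm <- c(2L, 3L, 1L)
  trp <- trm
  for (cc in c("target", "choice"))
    trp[[cc]] <- perm[trm[[cc]]]
  for (cc in c("flanker", "simon")) {
    v <- trm[[cc]]
    nz <- v > 0
    v[nz] <- perm[v[nz]]
    trp[[cc]] <- v
  }
  # start-point modifiers are positional, so keep positions fixed and
  # use position-neutral parameters
  expect_equal(dataset_loglik(mp, trm, "msit"), dataset_loglik(mp, trp, "msit"))
})
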