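# Synthetic designs and cohorts: structural properties of generated
# sequences, reproducibility, and the statistical signatures the task models
# imply (reversal dips, threshold/drift monotonicity).

test_that("reversal design swaps reward contingencies exactly at the reversal trial", {
  spec <- design_spec("rl_rev", blocks = 2, trials_per_block = 60,
                      reversal_trial = 30)
  d <- gen_design(spec, seed = 4)
  expect_equal(nrow(d), 120)
  pre <- d$trial <= 30
  expect_true(all(d$p1[pre] == 0.8 & d$p2[pre] == 0.2))
  expect_true(all(d$p1[!pre] == 0.2 & d$p2[!pre] == 0.8))
  expect_true(all(d$reward1 %in% 0:1))
  expect_error(design_spec("rl_rev", trials_per_block = 20,
                           reversal_trial = 30))
})

test_that("speed-accuracy design alternates emphasis with matched deadlines", {
  d <- gen_design(design_spec("rl_sat", blocks = 2, trials_per_block = 48,
                              miniblock = 12), seed = 2)
  expect_setequal(unique(d$emphasis), c("spd", "acc"))
  expect_equal(sum(d$emphasis == "spd"), 48)
  expect_true(all(d$deadline[d$emphasis == "spd"] == 0.7))
  expect_true(all(d$deadline[d$emphasis == "acc"] == 1.5))
  runs <- rle(d$emphasis[d$block == 1])
  expect_true(all(runs$lengths == 12))
})

test_that("reference-back transitions are consistent with the adjacent trials", {
  d <- gen_design(design_spec("rb", n_trials = 150), seed = 6)
  n <- nrow(d)
  expect_equal(d$type_trans[-1],
               ifelse(d$trial_type[-1] == d$trial_type[-n], 1L, 2L))
  expect_equal(d$stim_trans[-1],
               ifelse(d$stim[-1] == d$stim[-n], 1L, 2L))
  expect_equal(d$trial_type[1], 1L) # opens with a reference trial
  expect_true(all(d$correct_resp %in% 1:2))
})

test_that("interference design balances target positions and encodes conflict correctly", {
  d <- gen_design(design_spec("msit", n_trials = 120), seed = 3)
  expect_equal(as.integer(table(d$position)), rep(40L, 3))
  # flanker digit never equals the target; simon support is the position
  fl <- d$flanker > 0
  expect_true(all(d$flanker[fl] != d$target[fl]))
  si <- d$simon > 0
  expect_true(all(d$simon[si] == d$position[si]))
  expect_true(all(d$target[si] != d$position[si])) # spatial conflict trials
  neutral <- d$flanker == 0 & d$simon == 0
  expect_true(all(d$target[neutral] == d$position[neutral]))
})

test_that("subject generation is reproducible and honours the group structure", {
  co <- cohort_spec(8, tasks = "rb")
  s1 <- gen_subjects(co, seed = 10)
  s2 <- gen_subjects(co, seed = 10)
  expect_identical(s1$alpha, s2$alpha)
  # natural-scale constraints hold by construction of the transforms
  expect_true(all(s1$natural[, c("B_st1", "B_st2", "t0")] > 0))
  # degenerate covariance pins all subjects at the group mean
  tiny <- cohort_spec(5, tasks = "rb", Sigma = diag(1e-18, 9))
  st <- gen_subjects(tiny, seed = 1)
  expect_equal(max(abs(sweep(st$alpha, 2, tiny$mu))), 0, tolerance = 1e-6)
  # zero loadings leave cross-parameter correlations at sampling noise level
  lay <- param_layout("rb")
  z <- cohort_spec(500, tasks = "rb", structure = "factor",
                   Lambda = matrix(0, 9, 2), eps = rep(0.09, 9))
  sz <- gen_subjects(z, seed = 2)
  off <- cor(sz$alpha)[upper.tri(diag(9))]
  expect_lt(max(abs(off)), 0.15)
})

test_that("simulated cohorts carry complete records and respond to parameters as the model predicts", {
  co <- cohort_spec(2, tasks = "rb")
  tr <- simulate_cohort(co, list(rb = design_spec("rb", n_trials = 60)),
                        seed = 12)
  expect_true(all(c("subject", "task", "session", "block", "trial", "choice",
                    "rt_s", "correct") %in% names(tr)))
  expect_true(all(tr$rt_s > 0))
  expect_identical(tr, {
    t2 <- simulate_cohort(co, list(rb = design_spec("rb", n_trials = 60)),
                          seed = 12)
    attributes(t2) <- attributes(tr); t2
  })
  # dominance: huge sensitivity makes accuracy near-perfect
  pars <- c(V0_tt1 = 2, V0_tt2 = 2, delta_r1t1 = 12, delta_r2t1 = 12,
            delta_r1t2 = 12, delta_r2t2 = 12, B_st1 = 1.5, B_st2 = 1.5,
            t0 = 0.15)
  des <- gen_design(design_spec("rb", n_trials = 300), seed = 5)
  sim <- rdmjoint:::simulate_task_trials(pars, des, "rb", seed = 6)
  expect_gt(mean(sim$correct), 0.98)
})

test_that("median response time increases with threshold and accuracy with sensitivity", {
  base <- c(V0_tt1 = 2, V0_tt2 = 2, delta_r1t1 = 2, delta_r2t1 = 2,
            delta_r1t2 = 2, delta_r2t2 = 2, B_st1 = 1, B_st2 = 1, t0 = 0.15)
  des <- gen_design(design_spec("rb", n_trials = 800), seed = 20)
  med_rt <- acc <- numeric(3)
  for (i in seq_along(Bs <- c(0.7, 1.3, 2.2))) {
    p <- base
    p[c("B_st1", "B_st2")] <- Bs[i]
    sim <- rdmjoint:::simulate_task_trials(p, des, "rb", seed = 30 + i)
    med_rt[i] <- median(sim$rt_s)
  }
  expect_true(all(diff(med_rt) > 0))
  for (i in seq_along(ds <- c(0.4, 1.2, 3))) {
    p <- base
    p[grep("delta", names(p))] <- ds[i]
    sim <- rdmjoint:::simulate_task_trials(p, des, "rb", seed = 40 + i)
    acc[i] <- mean(sim$correct)
  }
  expect_true(all(diff(acc) > 0))
})

test_that("accuracy climbs before a reversal and dips right after it", {
  co <- cohort_spec(6, tasks = "rl_rev")
  tr <- simulate_cohort(co, list(rl_rev = design_spec(
    "rl_rev", blocks = 3, trials_per_block = 60, reversal_trial = 30)),
    seed = 14)
  late_acq <- tr$trial %in% 21:30   # learned, pre-reversal
  post_rev <- tr$trial %in% 31:40   # right after contingencies swap
  expect_gt(mean(tr$correct[late_acq]) - mean(tr$correct[post_rev]), 0.15)
  # deadline flags exist for the speed-accuracy task and are kept
  co2 <- cohort_spec(2, tasks = "rl_sat")
  tr2 <- simulate_cohort(co2, list(rl_sat = design_spec(
    "rl_sat", blocks = 1, trials_per_block = 48)), seed = 15)
  expect_true(all(tr2$deadline_exceeded %in% 0:1))
  expect_equal(tr2$deadline_exceeded, as.integer(tr2$rt_s > tr2$deadline))
})

test_that("two-session cohorts have the requested cross-session parameter correlation", {
  co <- cohort_spec(400, tasks = "rl_rev", sessions = 2, session_rho = 0.8)
  s <- gen_subjects(co, seed = 44)
  p <- 6
  rs <- vapply(seq_len(p), function(j)
    cor(s$alpha[, j], s$alpha[, p + j]), numeric(1))
  expect_true(all(abs(rs - 0.8) < 0.08))
  # sidecar round trip preserves the generating truth
  tr <- simulate_cohort(cohort_spec(2, tasks = "rb"),
                        list(rb = design_spec("rb", n_trials = 30)), seed = 2)
  dir <- tempfile()
  paths <- write_cohort(tr, dir)
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(side$n_subjects, 2)
  expect_equal(dim(side$alpha), dim(attr(tr, "truth")$alpha))
})
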