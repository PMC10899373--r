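## Data I/O, posterior summaries, and the two headline analyses: the
## between-session joint model (multivariate-normal group level, correlation
## extraction) and the between-task joint model (factor group level, loading
## summaries).

.required_cols <- c("subject", "task", "session", "block", "trial",
                    "choice", "rt_s")

#' Read and validate a trial table
#'
#' Checks required columns, positive response times and in-vocabulary
#' choices, and sorts by subject, task, session, block and trial. With
#' `chance_filter = TRUE`, subjects performing at or below chance accuracy
#' (1 / number of response options) in any session of a task are excluded
#' from that task, and the exclusions are reported in the `exclusions`
#' attribute.
#'
#' @param path CSV file path, or a data.frame.
#' @param chance_filter apply the above-chance inclusion rule.
#' @return validated trial data.frame (attribute `exclusions` when filtered).
#' @export
read_trials <- function(path, chance_filter = FALSE) {
  trials <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.required_cols, names(trials))
  if (length(miss))
    stop("trial table lacks required columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(trials$rt_s) | trials$rt_s <= 0)
  if (length(bad))
    stop("nonpositive or missing rt_s at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  n_choices <- ifelse(trials$task == "msit", 3L, 2L)
  badc <- which(trials$choice < 1 | trials$choice > n_choices)
  if (length(badc))
    stop("choice outside the task's response vocabulary at rows: ",
         paste(utils::head(badc, 10), collapse = ", "))
  trials <- trials[order(trials$subject, trials$task, trials$session,
                         trials$block, trials$trial), ]
  rownames(trials) <- NULL
  if (chance_filter) {
    if (is.null(trials$correct))
      stop("chance filter needs a `correct` column")
    acc <- aggregate(correct ~ subject + task + session, trials, mean)
    acc$chance <- ifelse(acc$task == "msit", 1 / 3, 1 / 2)
    drop <- unique(acc[acc$correct <= acc$chance, c("subject", "task")])
    if (nrow(drop)) {
      keep <- !(paste(trials$subject, trials$task) %in%
                  paste(drop$subject, drop$task))
      trials <- trials[keep, ]
    }
    attr(trials, "exclusions") <- drop
  }
  trials
}

#' Posterior summary table (equal-tailed 95% credible intervals)
#'
#' Linear-interpolation (type 7) quantiles at 2.5, 50 and 97.5%, with a flag
#' marking intervals that exclude zero (the bold-marking convention of the
#' reported tables).
#'
#' @param fit a `pmwg_fit`.
#' @param what `"means"` (group-level means, natural scale),
#'   `"correlations"` (implied correlations, off-diagonal pairs) or
#'   `"loadings"` (factor loadings, sign-aligned per column).
#' @return data.frame with columns `parameter`, `q2.5`, `q50`, `q97.5`,
#'   `excludes_zero`.
#' @export
summarize_posterior <- function(fit, what = c("means", "correlations",
                                              "loadings")) {
  what <- match.arg(what)
  dr <- stage_draws(fit)
  if (!length(dr$idx)) stop("no sampling-stage draws to summarise")
  qs <- function(x) quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  if (what == "means") {
    tr <- fit$model$transforms
    nat <- to_natural(dr$mu, tr)
    tab <- t(apply(nat, 2, qs))
    out <- data.frame(parameter = fit$param_names, q2.5 = tab[, 1],
                      q50 = tab[, 2], q97.5 = tab[, 3])
  } else if (what == "correlations") {
    p <- length(fit$param_names)
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    draws <- vapply(seq_along(dr$idx), function(i) {
      R <- stats::cov2cor(if (fit$group_kind == "mvn") dr$Sigma[, , i]
        else dr$Lambda[, , i] %*% t(dr$Lambda[, , i]) + diag(dr$eps[i, ], p))
      R[pairs]
    }, numeric(nrow(pairs)))
    draws <- matrix(draws, nrow = nrow(pairs))
    tab <- t(apply(draws, 1, qs))
    out <- data.frame(
      parameter = paste(fit$param_names[pairs[, 1]],
                        fit$param_names[pairs[, 2]], sep = " ~ "),
      q2.5 = tab[, 1], q50 = tab[, 2], q97.5 = tab[, 3])
  } else {
    if (fit$group_kind != "factor") stop("loadings need a factor-group fit")
    L <- align_loadings(dr$Lambda)
    p <- dim(L)[1]; k <- dim(L)[2]
    rows <- expand.grid(row = seq_len(p), col = seq_len(k))
    tab <- t(vapply(seq_len(nrow(rows)), function(i)
      qs(L[rows$row[i], rows$col[i], ]), numeric(3)))
    out <- data.frame(
      parameter = paste0(fit$param_names[rows$row], " (factor ", rows$col, ")"),
      q2.5 = tab[, 1], q50 = tab[, 2], q97.5 = tab[, 3])
  }
  out$excludes_zero <- out$q2.5 > 0 | out$q97.5 < 0
  rownames(out) <- NULL
  out
}

#' Between-session joint analysis of one task
#'
#' Fits the two-component joint model (one parameter set per session,
#' multivariate-normal group level), translates the group covariance draws
#' into correlations, and summarises (i) the correlations between the same
#' construct in the two sessions and (ii) the full correlation matrix with
#' its within/between-session partition.
#'
#' @param trials trial table containing two sessions of one task.
#' @param task the task id.
#' @param config a [sampler_config()].
#' @param seed integer seed.
#' @param ... passed to [fit_pmwg()].
#' @return list with the fit, `same_construct` summary table, the full
#'   correlation summary, and the per-draw same-construct correlation matrix.
#' @export
between_session_pipeline <- function(trials, task, config = sampler_config(),
                                     seed = 1L, ...) {
  trials <- trials[trials$task == task, ]
  if (length(unique(trials$session)) != 2)
    stop("between-session analysis needs exactly two sessions")
  s1 <- unique(trials$subject[trials$session == 1])
  s2 <- unique(trials$subject[trials$session == 2])
  common <- intersect(s1, s2)
  if (!length(common)) stop("no subjects appear in both sessions")
  trials <- trials[trials$subject %in% common, ]
  fit <- fit_joint(trials, tasks = task, pool_sessions = FALSE,
                   group = "mvn", config = config, seed = seed, ...)
  p <- length(task_param_names(task))
  dr <- stage_draws(fit)
  same <- vapply(seq_along(dr$idx), function(i) {
    R <- stats::cov2cor(dr$Sigma[, , i])
    R[cbind(seq_len(p), p + seq_len(p))]
  }, numeric(p))
  same <- matrix(same, nrow = p)
  qs <- t(apply(same, 1, quantile, c(0.025, 0.5, 0.975), type = 7,
                names = FALSE))
  same_tab <- data.frame(parameter = task_param_names(task),
                         q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3])
  same_tab$excludes_zero <- same_tab$q2.5 > 0 | same_tab$q97.5 < 0
  list(fit = fit, same_construct = same_tab,
       correlations = summarize_posterior(fit, "correlations"),
       same_construct_draws = same)
}

#' Between-task joint analysis with a factor-analytic group level
#'
#' Pools sessions within each task, concatenates the four task models into
#' one 31-parameter vector per subject, fits the factor joint model, and
#' summarises the sign-aligned loadings.
#'
#' @param trials trial table with the tasks to be analysed.
#' @param k number of latent factors.
#' @param tasks tasks to include (default all present).
#' @param config a [sampler_config()].
#' @param seed integer seed.
#' @param ... passed to [fit_pmwg()].
#' @return list with the fit and the loading summary table.
#' @export
between_task_pipeline <- function(trials, k = 2, tasks = NULL,
                                  config = sampler_config(), seed = 1L, ...) {
  if (k < 1) stop("`k` must be a positive factor count")
  fit <- fit_joint(trials, tasks = tasks, pool_sessions = TRUE,
                   group = "factor", k = k, config = config, seed = seed, ...)
  list(fit = fit, loadings = summarize_posterior(fit, "loadings"))
}
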