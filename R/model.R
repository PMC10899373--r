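## Model objects: a concatenated per-subject parameter vector, its sampling
## transforms, per-subject data, and a vectorised log-likelihood over
## candidate parameter matrices. Joint models are built by concatenating
## task/session components; custom models (arbitrary likelihood functions)
## support validation studies on conjugate toys.

#' Build a (joint) racing diffusion model from a trial table
#'
#' One component per task (sessions pooled, the between-task layout) or per
#' task-session combination (the between-session layout). The per-subject
#' parameter vector concatenates the components' parameters; the
#' log-likelihood is the sum of the component likelihoods. All subjects must
#' have trials in every component (complete-case design); violations raise an
#' error listing the subjects.
#'
#' @param trials a trial table (from [simulate_cohort()] or [read_trials()]).
#' @param tasks tasks to include (default: all present).
#' @param pool_sessions if `TRUE`, sessions contribute trials to one shared
#'   parameter set per task; if `FALSE`, each session gets its own parameter
#'   set (components are task-session pairs).
#' @return an object of class `rdm_model`.
#' @export
eam_model <- function(trials, tasks = NULL, pool_sessions = TRUE) {
  tasks <- tasks %||% intersect(TASKS, unique(trials$task))
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  trials <- trials[trials$task %in% tasks, ]
  sessions <- sort(unique(trials$session))
  n_sess <- if (pool_sessions) 1L else length(sessions)
  layout <- param_layout(tasks, sessions = n_sess)
  subjects <- sort(unique(trials$subject))
  ## complete-case audit
  comps <- expand.grid(task = tasks,
                       session = if (pool_sessions) NA else sessions,
                       stringsAsFactors = FALSE)
  missing <- character(0)
  for (s in subjects) for (i in seq_len(nrow(comps))) {
    sel <- trials$subject == s & trials$task == comps$task[i]
    if (!is.na(comps$session[i])) sel <- sel & trials$session == comps$session[i]
    if (!any(sel)) missing <- c(missing, paste0(s, "/", comps$task[i],
      if (!is.na(comps$session[i])) paste0("/s", comps$session[i])))
  }
  if (length(missing))
    stop("subjects missing component data: ", paste(missing, collapse = ", "))
  data <- lapply(subjects, function(s) {
    lapply(seq_len(nrow(comps)), function(i) {
      sel <- trials$subject == s & trials$task == comps$task[i]
      if (!is.na(comps$session[i]))
        sel <- sel & trials$session == comps$session[i]
      tr <- trials[sel, ]
      tr <- tr[order(tr$session, tr$block, tr$trial), ]
      sess_lab <- if (pool_sessions) 1L else
        match(comps$session[i], sessions)
      cols <- which(layout$map$task == comps$task[i] &
                    layout$map$session == sess_lab)
      list(enc = encode_trials(tr, comps$task[i]), cols = cols)
    })
  })
  structure(list(param_names = layout$names, transforms = layout$transforms,
                 layout = layout, subjects = subjects, data = data,
                 tasks = tasks, pool_sessions = pool_sessions,
                 fingerprint = model_fingerprint(trials),
                 loglik = NULL),
            class = "rdm_model")
}

## Cheap content fingerprint used to refuse Bayes factors across different
## datasets.
model_fingerprint <- function(trials) {
  c(n = nrow(trials), rt_sum = round(sum(trials$rt_s), 6),
    choice_sum = sum(trials$choice))
}

#' Build a custom hierarchical model from a likelihood function
#'
#' For validation studies: `loglik_fn(theta, data_s)` must accept a matrix of
#' sampling-scale parameter vectors (one per row) and one subject's data, and
#' return one log-likelihood per row.
#'
#' @param param_names parameter names.
#' @param data list with one element per subject.
#' @param loglik_fn vectorised log-likelihood function.
#' @param transforms named transform vector (default all identity).
#' @export
custom_model <- function(param_names, data, loglik_fn, transforms = NULL) {
  transforms <- transforms %||%
    setNames(rep("identity", length(param_names)), param_names)
  structure(list(param_names = param_names, transforms = transforms,
                 layout = NULL, subjects = seq_along(data), data = data,
                 fingerprint = c(n = length(data)), loglik = loglik_fn),
            class = "rdm_model")
}

## Evaluate the model log-likelihood for subject index s over a matrix of
## sampling-scale parameter vectors.
model_loglik <- function(model, theta, s) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (!is.null(model$loglik)) return(model$loglik(theta, model$data[[s]]))
  nat <- to_natural(theta, model$transforms)
  ll <- numeric(nrow(theta))
  for (comp in model$data[[s]]) {
    pm <- nat[, comp$cols, drop = FALSE]
    colnames(pm) <- model$layout$map$base[comp$cols]
    ll <- ll + task_loglik(pm, comp$enc)
  }
  ll
}
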