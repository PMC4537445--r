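# Virtual-subject necessity/sufficiency experiments.
#
# Large cohorts of identical virtual subjects are simulated per group under
# "constraint schemes": each scheme lets a chosen subset of the winning
# model's parameters take group-specific values while the rest are pinned
# to the pooled (all-subject) value. A scheme is sufficient for a
# behavioural effect if the virtual groups reproduce it (Welch test at
# alpha, in the expected direction); a parameter is necessary for the
# effect if no scheme excluding it is sufficient.

#' Task configuration of the virtual experiment
#'
#' The simulation protocol: valid-reinforcement probability 0.8, 30 trials
#' per session, stopping criterion 90% correct, capped at 100 sessions.
#'
#' @param stage_id label for the virtual stage.
#' @return A [stage_config()].
#' @export
virtual_task_config <- function(stage_id = "V1") {
  stage_config(stage_id, p_valid = 0.8, trials_per_session = 30L,
               criterion = 0.9, max_sessions = 100L)
}

#' Simulate one virtual group and compute its behavioural measures
#'
#' Every virtual subject takes the same parameter values and performs one
#' discrimination stage; errors to criterion and the probabilities of
#' obeying true and false feedback are computed from the simulated logs.
#'
#' @param params parameter set shared by all virtual subjects.
#' @param spec a `pvdrl_spec`.
#' @param n_virtual number of virtual subjects.
#' @param task_cfg a [stage_config()]; default [virtual_task_config()].
#' @param seed integer seed.
#' @param group group label recorded in the output.
#' @return Data frame, one row per virtual subject: subject, group,
#'   errors, sqrt_errors, attained, obey_true, obey_false.
#' @export
run_virtual_group <- function(params, spec, n_virtual = 1000L,
                              task_cfg = virtual_task_config(), seed = 1L,
                              group = "virtual") {
  stopifnot(n_virtual >= 1L)
  params <- param_set(params, spec = spec)
  logs <- vector("list", n_virtual)
  for (i in seq_len(n_virtual)) {
    set.seed(as.integer((seed + 2654435 * i) %% 2147483647))
    logs[[i]] <- as.data.frame(simulate_stage(
      params, spec, task_cfg, subject = sprintf("v%04d", i),
      group = group))
  }
  trials <- do.call(rbind, logs)
  err <- errors_to_criterion(trials, task_cfg$criterion)
  ob <- obey_analysis(trials)
  obey_by_ver <- function(ver) {
    d <- ob[ob$prev_veracity == ver, , drop = FALSE]
    agg <- tapply(d$obey_prob * d$n_pairs, d$subject, sum) /
      tapply(d$n_pairs, d$subject, sum)
    agg[match(err$subject, names(agg))]
  }
  data.frame(subject = err$subject, group = group, errors = err$errors,
             sqrt_errors = sqrt_errors(err$errors),
             attained = err$attained,
             obey_true = as.numeric(obey_by_ver(TRUE)),
             obey_false = as.numeric(obey_by_ver(FALSE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enumerate parameter constraint schemes
#'
#' All subsets of the parameter set, from the all-fixed null scheme to the
#' all-varying scheme (`2^P` schemes for `P` parameters).
#'
#' @param parameters character vector of parameter names.
#' @return Named list of character vectors (the varying subset of each
#'   scheme); the null scheme is named `"none"`.
#' @export
constraint_schemes <- function(parameters) {
  P <- length(parameters)
  schemes <- lapply(0:(2^P - 1), function(m)
    parameters[bitwAnd(m, 2^(seq_len(P) - 1)) > 0])
  names(schemes) <- vapply(schemes, function(v)
    if (!length(v)) "none" else paste(v, collapse = "+"), character(1))
  schemes
}

#' Necessity/sufficiency analysis over constraint schemes
#'
#' For each scheme, each varying parameter takes its group-specific value
#' and each fixed parameter the pooled value; the virtual groups are then
#' simulated and compared pairwise with Welch two-sample tests on
#' square-root errors to criterion and on the obey-true and obey-false
#' probabilities. A scheme is sufficient for an effect when the difference
#' is significant at `alpha` in the expected direction; expected
#' directions are supplied, or inferred from the all-varying scheme's
#' significant effects. A parameter is necessary for an effect when no
#' scheme excluding it is sufficient.
#'
#' @param group_params named list (>= 2 groups) of parameter sets.
#' @param pooled_params the all-subject pooled parameter set.
#' @param spec a `pvdrl_spec`.
#' @param schemes list of varying-parameter subsets; default all of
#'   [constraint_schemes()].
#' @param n_virtual virtual subjects per group.
#' @param task_cfg a [stage_config()].
#' @param alpha test level in (0, 1).
#' @param directions optional data frame (pair, measure, sign) of expected
#'   effect directions; sign is the expected sign of `groupA - groupB`
#'   with pairs labelled `"A-B"`.
#' @param seed integer seed.
#' @return A `pvdrl_virtual` list: `results` (scheme x pair x measure
#'   grid with differences, p-values and sufficiency), `directions`,
#'   `necessity` (parameter x effect grid), `measures`.
#' @export
necessity_sufficiency <- function(group_params, pooled_params, spec,
                                  schemes = NULL, n_virtual = 1000L,
                                  task_cfg = virtual_task_config(),
                                  alpha = 0.05, directions = NULL,
                                  seed = 1L) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (length(group_params) < 2L)
    stop("need at least two groups")
  if (is.null(names(group_params)) || anyDuplicated(names(group_params)))
    stop("group_params must be uniquely named")
  nm <- param_names(spec)
  pooled <- param_set(pooled_params, spec = spec)
  group_params <- lapply(group_params, param_set, spec = spec)
  if (is.null(schemes)) schemes <- constraint_schemes(nm)
  scheme_names <- names(schemes) %||%
    vapply(schemes, function(v)
      if (!length(v)) "none" else paste(v, collapse = "+"), character(1))
  measures <- c("errors", "obey_true", "obey_false")
  col_of <- c(errors = "sqrt_errors", obey_true = "obey_true",
              obey_false = "obey_false")
  glabels <- names(group_params)
  pairs <- utils::combn(glabels, 2, simplify = FALSE)

  run_scheme <- function(varying, k) {
    sims <- lapply(seq_along(glabels), function(gi) {
      p <- pooled
      p[varying] <- group_params[[gi]][varying]
      run_virtual_group(p, spec, n_virtual, task_cfg,
                        seed = seed + 1009L * k + gi,
                        group = glabels[gi])
    })
    names(sims) <- glabels
    rows <- list()
    for (pr in pairs) {
      for (ms in measures) {
        # subjects with no pairs in a cell have no measure value there
        a <- sims[[pr[1]]][[col_of[ms]]]
        b <- sims[[pr[2]]][[col_of[ms]]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        tt <- t.test(a, b)   # Welch by default
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme_names[k], pair = paste(pr, collapse = "-"),
          measure = ms, diff = mean(a) - mean(b),
          p_value = tt$p.value, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  results <- do.call(rbind, lapply(seq_along(schemes), function(k)
    run_scheme(schemes[[k]], k)))
  results$significant <- results$p_value < alpha

  if (is.null(directions)) {
    full <- scheme_names[which.max(lengths(schemes))]
    ref <- results[results$scheme == full & results$significant, ,
                   drop = FALSE]
    directions <- data.frame(pair = ref$pair, measure = ref$measure,
                             sign = sign(ref$diff),
                             stringsAsFactors = FALSE)
  }
  key <- function(d) paste(d$pair, d$measure)
  dir_sign <- setNames(directions$sign, key(directions))
  expected <- dir_sign[key(results)]
  results$sufficient <- results$significant &
    !is.na(expected) & sign(results$diff) == expected

  effects <- unique(key(directions))
  necessity <- NULL
  if (length(effects)) {
    necessity <- expand.grid(parameter = nm, effect = effects,
                             stringsAsFactors = FALSE)
    necessity$necessary <- vapply(seq_len(nrow(necessity)), function(i) {
      p <- necessity$parameter[i]
      excl <- scheme_names[!vapply(schemes, function(v) p %in% v,
                                   logical(1))]
      sub <- results[results$scheme %in% excl &
                       key(results) == necessity$effect[i], , drop = FALSE]
      !any(sub$sufficient)
    }, logical(1))
  }
  structure(list(results = results, directions = directions,
                 necessity = necessity, measures = measures,
                 alpha = alpha, n_virtual = n_virtual),
            class = "pvdrl_virtual")
}

#' @export
print.pvdrl_virtual <- function(x, ...) {
  cat("Virtual necessity/sufficiency analysis:",
      length(unique(x$results$scheme)), "schemes,", x$n_virtual,
      "virtual subjects per group, alpha =", x$alpha, "\n")
  suff <- x$results[x$results$sufficient, c("scheme", "pair", "measure")]
  if (nrow(suff)) {
    cat("Sufficient schemes:\n")
    print(suff, row.names = FALSE)
  } else cat("No sufficient schemes.\n")
  invisible(x)
}
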