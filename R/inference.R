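# Parameter estimation for the model family.
#
# Two routes: per-subject MAP (optimisation of log-likelihood + log prior,
# group level collapsed to the prior) and hierarchical Bayesian estimation
# by random-walk Metropolis-within-Gibbs. The hierarchy follows the
# task's standard formulation: each subject's parameter is drawn from a
# normal with a group-specific mean and a group-shared, parameter-specific
# SD, truncated to the parameter's support; group-mean rates have a
# Beta(1.1, 1.1) prior, group-mean stickiness maxima a Gamma(shape 1.2,
# rate 0.2) prior, and the SDs a positive half-Cauchy(0, 5) prior.

#' Hierarchical prior specification
#'
#' @param beta_a,beta_b Beta prior on group-mean rates.
#' @param gamma_shape,gamma_rate Gamma prior on group-mean stickiness
#'   maxima (`rate`, so the default scale is 5).
#' @param cauchy_scale scale of the positive half-Cauchy prior on the
#'   group-shared SDs.
#' @return A `pvdrl_prior` list.
#' @export
hier_prior <- function(beta_a = 1.1, beta_b = 1.1, gamma_shape = 1.2,
                       gamma_rate = 0.2, cauchy_scale = 5) {
  structure(list(beta_a = beta_a, beta_b = beta_b,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 cauchy_scale = cauchy_scale),
            class = "pvdrl_prior")
}

log_prior_natural <- function(th, is_rate, prior) {
  lp <- numeric(length(th))
  lp[is_rate] <- dbeta(th[is_rate], prior$beta_a, prior$beta_b, log = TRUE)
  lp[!is_rate] <- dgamma(th[!is_rate], shape = prior$gamma_shape,
                         rate = prior$gamma_rate, log = TRUE)
  sum(lp)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

to_natural <- function(eta, is_rate) {
  out <- numeric(length(eta))
  out[is_rate] <- inv_logit(eta[is_rate])
  out[!is_rate] <- exp(eta[!is_rate])
  out
}

to_transformed <- function(th, is_rate) {
  out <- numeric(length(th))
  out[is_rate] <- logit(th[is_rate])
  out[!is_rate] <- log(th[!is_rate])
  out
}

draw_from_prior <- function(nm, prior) {
  is_rate <- param_is_rate(nm)
  setNames(ifelse(is_rate,
                  rbeta(length(nm), prior$beta_a, prior$beta_b),
                  stats::rgamma(length(nm), shape = prior$gamma_shape,
                                rate = prior$gamma_rate)), nm)
}

#' Maximum a posteriori fit, per subject
#'
#' Each subject is optimised independently; the objective is the trial
#' log-likelihood plus the log prior density of the parameters (the group
#' level collapsed to the prior). Optimisation runs on a transformed scale
#' (logit for rates, log for maxima) from `n_starts` prior-drawn starting
#' points, keeping the best converged result.
#'
#' @param trials cohort trial log.
#' @param spec a `pvdrl_spec`.
#' @param prior a [hier_prior()].
#' @param n_starts multistart count.
#' @param seed integer; makes the starts (and hence the fit) deterministic.
#' @return A `pvdrl_map` list: `params` (per-subject named vectors),
#'   `loglik` (data log-likelihood at the MAP point, per subject),
#'   `logpost`, `flagged` (per subject, `TRUE` if no start converged),
#'   `spec`.
#' @export
map_fit <- function(trials, spec, prior = hier_prior(), n_starts = 16L,
                    seed = 1L) {
  dat <- encode_trials(trials)
  nm <- param_names(spec)
  is_rate <- param_is_rate(nm)
  p6 <- function(th) par6(setNames(th, nm), spec)
  fits <- lapply(seq_along(dat$enc), function(si) {
    enc <- dat$enc[[si]]
    negobj <- function(eta) {
      th <- to_natural(eta, is_rate)
      if (any(!is.finite(th))) return(1e10)
      lp <- log_prior_natural(th, is_rate, prior)
      if (!is.finite(lp)) return(1e10)
      ll <- rl_loglik_cpp(enc$chosen, enc$side1, enc$reinf, enc$reset,
                          p6(th), spec$stim_stickiness,
                          spec$side_stickiness)
      -(ll + lp)
    }
    set.seed((seed + 7919L * si) %% .Machine$integer.max)
    best <- NULL
    for (k in seq_len(n_starts)) {
      start <- draw_from_prior(nm, prior)
      start[is_rate] <- pmin(pmax(start[is_rate], 0.02), 0.98)
      start[!is_rate] <- pmax(start[!is_rate], 0.05)
      res <- tryCatch(
        optim(to_transformed(start, is_rate), negobj, method = "BFGS",
              control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best))
      return(list(params = setNames(rep(NA_real_, length(nm)), nm),
                  loglik = NA_real_, logpost = NA_real_, flagged = TRUE))
    th <- setNames(to_natural(best$par, is_rate), nm)
    ll <- rl_loglik_cpp(enc$chosen, enc$side1, enc$reinf, enc$reset,
                        p6(th), spec$stim_stickiness, spec$side_stickiness)
    list(params = th, loglik = ll, logpost = -best$value, flagged = FALSE)
  })
  names(fits) <- dat$subjects
  structure(list(
    params = lapply(fits, `[[`, "params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    logpost = vapply(fits, `[[`, numeric(1), "logpost"),
    flagged = vapply(fits, `[[`, logical(1), "flagged"),
    spec = spec, subjects = dat$subjects, groups = dat$groups),
    class = "pvdrl_map")
}

#' Hierarchical Bayesian fit
#'
#' Random-walk Metropolis-within-Gibbs over subject-level parameters,
#' group means and group-shared SDs (see the package vignette for the
#' model statement). Proposal scales adapt during warmup only. The
#' per-draw total data log-likelihood is stored alongside the samples; its
#' posterior mean is the `LL` entering model comparison.
#'
#' @param trials cohort trial log (each subject in exactly one group, at
#'   least one trial per subject). May be `NULL` only with
#'   `prior_only = TRUE`.
#' @param spec a `pvdrl_spec`.
#' @param prior a [hier_prior()].
#' @param chains number of chains (>= 2).
#' @param warmup,iter warmup and kept iterations per chain.
#' @param seed integer seed (mandatory).
#' @param prior_only drop the likelihood term and sample the prior; used
#'   for prior-predictive checks. Requires `subjects`/`groups` if `trials`
#'   is `NULL`.
#' @param subjects,groups subject ids and their group labels, normally
#'   taken from `trials`.
#' @param rhat_threshold convergence flag threshold on split-chain R-hat.
#' @return A `pvdrl_fit` with elements `draws` (arrays `mu[iter, chain,
#'   group, param]`, `sigma[iter, chain, param]`, `theta[iter, chain,
#'   subject, param]`, `loglik[iter, chain]`), `diagnostics` (R-hat and
#'   effective sample size per quantity), `flagged`, and `meta`.
#' @export
hierarchical_fit <- function(trials, spec, prior = hier_prior(),
                             chains = 4L, warmup = 1000L, iter = 1000L,
                             seed, prior_only = FALSE, subjects = NULL,
                             groups = NULL, rhat_threshold = 1.05) {
  if (missing(seed)) stop("seed is mandatory")
  if (chains < 2L) stop("at least 2 chains are required")
  if (is.null(trials)) {
    if (!prior_only)
      stop("trials with at least one trial per subject are required")
    if (is.null(subjects)) { subjects <- "s1"; groups <- "g1" }
    enc_list <- rep(list(NULL), length(subjects))
  } else {
    dat <- encode_trials(trials)
    if (any(vapply(dat$enc, function(e) length(e$chosen), integer(1)) == 0L))
      stop("every subject needs at least one trial")
    enc_list <- dat$enc; subjects <- dat$subjects; groups <- dat$groups
  }
  if (is.null(groups)) groups <- rep("g1", length(subjects))
  group_levels <- unique(groups)
  gidx <- match(groups, group_levels)
  nm <- param_names(spec)
  is_rate <- param_is_rate(nm)
  z <- length(nm); S <- length(subjects); G <- length(group_levels)

  run_chain <- function(chain) {
    set.seed((seed + 104729L * chain) %% .Machine$integer.max)
    init_mu <- matrix(0, G, z)
    for (g in seq_len(G)) {
      d <- draw_from_prior(nm, hier_prior())
      d[is_rate] <- pmin(pmax(d[is_rate], 0.1), 0.9)
      d[!is_rate] <- pmin(pmax(d[!is_rate], 0.2), 4)
      init_mu[g, ] <- d
    }
    init_sigma <- runif(z, 0.2, 0.8)
    init_theta <- matrix(0, S, z)
    for (s in seq_len(S))
      for (j in seq_len(z))
        init_theta[s, j] <- rtnorm(1, init_mu[gidx[s], j], init_sigma[j],
                                   0, if (is_rate[j]) 1 else Inf)
    rl_hier_sampler_cpp(enc_list, gidx, G, spec$stim_stickiness,
                        spec$side_stickiness, param_slots(spec), is_rate,
                        init_theta, init_mu, init_sigma, warmup, iter,
                        prior$beta_a, prior$beta_b, prior$gamma_shape,
                        1 / prior$gamma_rate, prior$cauchy_scale,
                        prior_only)
  }
  res <- lapply(seq_len(chains), run_chain)

  mu <- array(NA_real_, c(iter, chains, G, z),
              dimnames = list(NULL, NULL, group_levels, nm))
  sigma <- array(NA_real_, c(iter, chains, z),
                 dimnames = list(NULL, NULL, nm))
  theta <- array(NA_real_, c(iter, chains, S, z),
                 dimnames = list(NULL, NULL, subjects, nm))
  loglik <- matrix(NA_real_, iter, chains)
  for (ch in seq_len(chains)) {
    mu[, ch, , ] <- reshape_draws(res[[ch]]$mu, iter, z, G)
    sigma[, ch, ] <- res[[ch]]$sigma
    theta[, ch, , ] <- reshape_draws(res[[ch]]$theta, iter, z, S)
    loglik[, ch] <- res[[ch]]$loglik
  }

  diag <- fit_diagnostics(mu, sigma, loglik, group_levels, nm)
  structure(list(
    draws = list(mu = mu, sigma = sigma, theta = theta, loglik = loglik),
    diagnostics = diag,
    flagged = any(diag$rhat > rhat_threshold, na.rm = TRUE),
    meta = list(spec = spec, prior = prior, subjects = subjects,
                groups = groups, group_levels = group_levels, seed = seed,
                chains = chains, warmup = warmup, iter = iter,
                prior_only = prior_only)),
    class = "pvdrl_fit")
}

# sampler matrices have column index u*z + j (parameter fastest within
# unit); reshape to [iter, unit, param]
reshape_draws <- function(mat, iter, z, units) {
  aperm(array(mat, c(iter, z, units)), c(1, 3, 2))
}

fit_diagnostics <- function(mu, sigma, loglik, group_levels, nm) {
  rows <- list()
  for (g in seq_along(group_levels))
    for (j in seq_along(nm))
      rows[[length(rows) + 1L]] <-
        data.frame(quantity = sprintf("mu[%s,%s]", group_levels[g], nm[j]),
                   rhat = split_rhat(mu[, , g, j]),
                   ess = ess_basic(mu[, , g, j]))
  for (j in seq_along(nm))
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = sprintf("sigma[%s]", nm[j]),
                 rhat = split_rhat(sigma[, , j]),
                 ess = ess_basic(sigma[, , j]))
  rows[[length(rows) + 1L]] <-
    data.frame(quantity = "loglik", rhat = split_rhat(loglik),
               ess = ess_basic(loglik))
  do.call(rbind, rows)
}

#' Split-chain potential scale reduction factor
#'
#' @param x matrix of draws, iterations x chains.
#' @return R-hat (scalar); `NA` for constant draws.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[(nrow(x) - n + 1L):nrow(x), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial positive sequence, pooled
# across chains on the within-chain autocorrelation
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(x, 2, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  max_lag <- min(n - 2L, 200L)
  rho <- rep(0, max_lag)
  for (ch in seq_len(m)) {
    v <- x[, ch] - mean(x[, ch])
    ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                     demean = FALSE)$acf[-1]
    rho <- rho + ac / m
  }
  tau <- 1
  for (k in seq(1, max_lag - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
  }
  n * m / tau
}

#' @export
print.pvdrl_fit <- function(x, ...) {
  cat("Hierarchical fit:", spec_label(x$meta$spec), "|",
      length(x$meta$subjects), "subjects in",
      length(x$meta$group_levels), "group(s) |", x$meta$chains, "chains x",
      x$meta$iter, "kept draws\n")
  if (x$flagged)
    cat("WARNING: convergence flagged (max split R-hat ",
        round(max(x$diagnostics$rhat, na.rm = TRUE), 3), ")\n", sep = "")
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `pvdrl_fit`.
#' @param mass HDI mass for the interval columns.
#' @param ... unused.
#' @return Data frame: quantity, mean, sd, HDI bounds, R-hat, ESS.
#' @export
summary.pvdrl_fit <- function(object, mass = 0.95, ...) {
  draws <- object$draws
  nm <- param_names(object$meta$spec)
  gl <- object$meta$group_levels
  rows <- list()
  add <- function(q, v) {
    h <- hdi(v, mass)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = q, mean = mean(v), sd = sd(v), hdi_lower = h[1],
      hdi_upper = h[2])
  }
  for (g in seq_along(gl))
    for (j in seq_along(nm))
      add(sprintf("mu[%s,%s]", gl[g], nm[j]), as.vector(draws$mu[, , g, j]))
  for (j in seq_along(nm))
    add(sprintf("sigma[%s]", nm[j]), as.vector(draws$sigma[, , j]))
  add("loglik", as.vector(draws$loglik))
  out <- do.call(rbind, rows)
  merge(out, object$diagnostics, by = "quantity", all.x = TRUE,
        sort = FALSE)
}

#' Write a posterior summary as tab-separated text
#'
#' @param fit a `pvdrl_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples; ties go to the lowest left endpoint.
#'
#' @param samples numeric vector (>= 10 values).
#' @param mass interval mass in (0, 1).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(mass) != 1 || !is.finite(mass) || mass <= 0 || mass >= 1)
    stop("mass must lie strictly between 0 and 1")
  x <- sort(samples)
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Posterior probability that a quantity is nonzero
#'
#' The largest HDI mass `w` such that the `w`-HDI excludes zero, located by
#' bisection to a resolution of 0.001 and reported with floor/ceiling
#' 0.001/0.999.
#'
#' @param samples numeric vector of draws (e.g. of a group difference).
#' @param resolution bisection resolution.
#' @return Scalar in `[0.001, 0.999]`.
#' @export
p_nz <- function(samples, resolution = 0.001) {
  excl <- function(w) {
    h <- hdi(samples, w)
    h[1] > 0 || h[2] < 0
  }
  lo <- resolution; hi <- 1 - resolution
  if (!excl(lo)) return(resolution)
  if (excl(hi)) return(1 - resolution)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (excl(mid)) lo <- mid else hi <- mid
  }
  round(lo / resolution) * resolution
}

#' Posterior difference between two group means
#'
#' Computed draw-wise as `mean(groupA) - mean(groupB)`.
#'
#' @param fit a `pvdrl_fit`.
#' @param parameter parameter name (one of `param_names()` of the fitted
#'   spec).
#' @param group_a,group_b group labels present in the fit.
#' @param mass HDI mass for the reported interval.
#' @return List: `samples`, `mean`, `hdi`, `p_nz`.
#' @export
group_difference <- function(fit, parameter, group_a, group_b,
                             mass = 0.95) {
  stopifnot(inherits(fit, "pvdrl_fit"))
  nm <- param_names(fit$meta$spec)
  gl <- fit$meta$group_levels
  if (!parameter %in% nm) stop("unknown parameter: ", parameter)
  if (!all(c(group_a, group_b) %in% gl))
    stop("unknown group label")
  d <- as.vector(fit$draws$mu[, , group_a, parameter]) -
    as.vector(fit$draws$mu[, , group_b, parameter])
  list(samples = d, mean = mean(d), hdi = hdi(d, mass), p_nz = p_nz(d))
}

#' Model-derived probabilities of obeying previous feedback
#'
#' For every consecutive within-session trial pair, the model's
#' probability (under the subject's sampled parameters, averaged over
#' posterior draws) of making the choice that obeys the previous trial's
#' feedback: staying with the previous stimulus after reward, shifting
#' after punishment. Pairs are averaged within cells of the previous
#' trial's valence x veracity.
#'
#' @param fit a `pvdrl_fit`, a `pvdrl_map`, or a named list of per-subject
#'   parameter vectors (point evaluation; requires `spec`).
#' @param trials the trial log the probabilities are evaluated on (the
#'   same subjects as `fit`).
#' @param spec required when `fit` is a plain parameter list.
#' @param max_draws posterior draws used per subject (evenly thinned).
#' @return Data frame: subject, prev_valence, prev_veracity, obey_prob,
#'   n_pairs. Cells with no pairs are absent.
#' @export
model_obey_probabilities <- function(fit, trials, spec = NULL,
                                     max_draws = 200L) {
  if (inherits(fit, "pvdrl_fit")) {
    spec <- fit$meta$spec
    theta_of <- function(subject) {
      th <- fit$draws$theta[, , subject, , drop = FALSE]
      d <- dim(th)
      m <- matrix(th, d[1] * d[2], d[4])
      colnames(m) <- param_names(spec)
      keep <- unique(round(seq(1, nrow(m),
                               length.out = min(max_draws, nrow(m)))))
      m[keep, , drop = FALSE]
    }
  } else if (inherits(fit, "pvdrl_map")) {
    spec <- fit$spec
    theta_of <- function(subject) t(as.matrix(fit$params[[subject]]))
  } else {
    if (is.null(spec)) stop("spec is required with a plain parameter list")
    theta_of <- function(subject)
      t(as.matrix(param_set(fit[[subject]], spec = spec)))
  }
  trials <- validate_trials(trials)
  out <- list()
  for (subject in unique(trials$subject)) {
    tr <- trials[trials$subject == subject, , drop = FALSE]
    enc <- encode_subject(tr)
    n <- nrow(tr)
    if (n < 2L) next
    same <- tr$stage[-1] == tr$stage[-n] & tr$session[-1] == tr$session[-n]
    if (!any(same)) next
    th <- theta_of(subject)
    obey_sum <- numeric(n - 1L)
    for (k in seq_len(nrow(th))) {
      p <- rl_probs_cpp(enc$chosen, enc$side1, enc$reinf, enc$reset,
                        par6(th[k, ], spec), spec$stim_stickiness,
                        spec$side_stickiness)
      stay <- p[cbind(2:n, enc$chosen[-n])]
      obey_sum <- obey_sum +
        ifelse(enc$reinf[-n] > 0, stay, 1 - stay)
    }
    obey <- (obey_sum / nrow(th))[same]
    prev_val <- ifelse(tr$outcome[-n] == "reward", "reward",
                       "punish")[same]
    prev_ver <- tr$veracity[-n][same]
    agg <- aggregate(obey, list(prev_valence = prev_val,
                                prev_veracity = prev_ver), mean)
    cnt <- aggregate(obey, list(prev_valence = prev_val,
                                prev_veracity = prev_ver), length)
    agg$n_pairs <- cnt$x
    agg$subject <- subject
    names(agg)[names(agg) == "x"] <- "obey_prob"
    out[[length(out) + 1L]] <-
      agg[, c("subject", "prev_valence", "prev_veracity", "obey_prob",
              "n_pairs")]
  }
  if (!length(out))
    stop("no within-session trial pairs available")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
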