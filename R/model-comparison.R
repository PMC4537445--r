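# Penalized model comparison across the eight-member family.
# BIC = -2 LL + k ln(n); AICc = (2k - 2 LL) + 2k(k+1)/(n - k - 1), with
# k = z s (parameters per subject times subjects) and n the total trial
# count. LL is either the posterior mean of the per-draw total
# log-likelihood (hierarchical mode) or the data log-likelihood at the
# MAP point (MAP mode).

#' Bayesian information criterion
#'
#' @param LL log-likelihood.
#' @param k total parameter count (`z * s`).
#' @param n total number of trials.
#' @return `-2 * LL + k * log(n)`.
#' @export
bic <- function(LL, k, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0)) stop("k must be nonnegative")
  -2 * LL + k * log(n)
}

#' Corrected Akaike information criterion
#'
#' @inheritParams bic
#' @return `(2 * k - 2 * LL) + 2 * k * (k + 1) / (n - k - 1)`.
#' @export
aicc <- function(LL, k, n) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1")
  (2 * k - 2 * LL) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and score every model in a family
#'
#' Each spec is fitted to the cohort (`method = "map"`: per-subject MAP,
#' with `LL` the summed data log-likelihood at the MAP points;
#' `method = "hierarchical"`: the full hierarchical model, with `LL` the
#' posterior mean of the per-draw total log-likelihood), then scored by
#' BIC with an AICc cross-check. The winner is the lowest BIC; ties break
#' to smaller `k`, then family order. Specs whose fit fails are flagged
#' and excluded from winner selection with a warning.
#'
#' @param trials cohort trial log.
#' @param family list of `pvdrl_spec`s (default [model_family()]).
#' @param method `"map"` or `"hierarchical"`.
#' @param prior a [hier_prior()].
#' @param seed integer seed.
#' @param ... further arguments to [map_fit()] or [hierarchical_fit()]
#'   (e.g. `n_starts`, `chains`, `warmup`, `iter`).
#' @return Data frame with one row per spec (model, z, s, k, n, LL, BIC,
#'   AICc, winner flag, AICc agreement) and attribute `winner` (the
#'   winning `pvdrl_spec`).
#' @export
compare_models <- function(trials, family = model_family(),
                           method = c("map", "hierarchical"),
                           prior = hier_prior(), seed = 1L, ...) {
  method <- match.arg(method)
  if (!length(family)) stop("family must be non-empty")
  trials <- validate_trials(trials)
  s <- length(unique(trials$subject))
  n <- nrow(trials)
  rows <- lapply(seq_along(family), function(i) {
    spec <- family[[i]]
    z <- n_params(spec)
    k <- z * s
    LL <- tryCatch({
      if (method == "map") {
        fit <- map_fit(trials, spec, prior, seed = seed, ...)
        if (any(fit$flagged)) NA_real_ else sum(fit$loglik)
      } else {
        fit <- hierarchical_fit(trials, spec, prior, seed = seed, ...)
        mean(fit$draws$loglik)
      }
    }, error = function(e) NA_real_)
    data.frame(model = spec_label(spec), z = z, s = s, k = k, n = n,
               LL = LL, bic = if (is.na(LL)) NA_real_ else bic(LL, k, n),
               aicc = if (is.na(LL)) NA_real_ else aicc(LL, k, n),
               failed = is.na(LL), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$failed))
    warning("excluded failed fits from winner selection: ",
            paste(tab$model[tab$failed], collapse = ", "))
  ok <- which(!tab$failed)
  if (!length(ok)) stop("all model fits failed")
  ord <- ok[order(tab$bic[ok], tab$k[ok], ok)]
  win <- ord[1]
  tab$winner <- seq_len(nrow(tab)) == win
  ord_a <- ok[order(tab$aicc[ok], tab$k[ok], ok)]
  tab$aicc_agrees <- ord_a[1] == win
  structure(tab, winner = family[[win]])
}
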