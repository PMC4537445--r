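# Model-free behavioural measures: errors to criterion (with square-root
# transform) and the win-stay/lose-shift "obey" analysis split by the
# previous trial's valence and veracity.

#' Errors to criterion for each subject x stage
#'
#' Sums incorrect choices over the sessions strictly before the first
#' session whose correct fraction reaches `criterion` (the criterion day
#' itself is excluded); zero if the first session already meets it. If the
#' criterion is never met, the total error count is returned with
#' `attained = FALSE`.
#'
#' @param trials trial log (any number of subjects/stages).
#' @param criterion session correct fraction (compared with `>=`).
#' @return Data frame: subject, group, stage, errors, sessions, attained.
#' @export
errors_to_criterion <- function(trials, criterion = 0.9) {
  trials <- validate_trials(trials)
  correct <- trials$choice_stim == trials$correct_stim
  out <- list()
  for (subject in unique(trials$subject)) {
    tr_s <- trials$subject == subject
    for (stage in unique(trials$stage[tr_s])) {
      idx <- tr_s & trials$stage == stage
      ses <- trials$session[idx]
      ord <- sort(unique(ses))
      frac <- vapply(ord, function(s) mean(correct[idx][ses == s]),
                     numeric(1))
      errs <- vapply(ord, function(s) sum(!correct[idx][ses == s]),
                     numeric(1))
      hit <- which(frac >= criterion)
      if (length(hit)) {
        n_err <- if (hit[1] == 1L) 0L else sum(errs[seq_len(hit[1] - 1L)])
        attained <- TRUE
      } else {
        n_err <- sum(errs)
        attained <- FALSE
      }
      out[[length(out) + 1L]] <- data.frame(
        subject = subject, group = trials$group[idx][1], stage = stage,
        errors = as.integer(n_err), sessions = length(ord),
        attained = attained, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Square-root transform of error counts
#'
#' The standard variance-stabilising transform for counts whose variance
#' grows with the mean.
#'
#' @param errors nonnegative numeric vector.
#' @return `sqrt(errors)`.
#' @export
sqrt_errors <- function(errors) {
  if (any(errors < 0)) stop("errors must be nonnegative")
  sqrt(errors)
}

#' Win-stay/lose-shift "obey" analysis by valence and veracity
#'
#' Every trial is matched with the immediately preceding trial within the
#' same session. The subject "obeyed" the previous feedback if it stayed
#' with the same stimulus after reward or switched after punishment.
#' Pairs are tabulated by the previous trial's valence (reward/punish)
#' and veracity (true = congruent with the contingency in force on that
#' trial), separately for discrimination and reversal stages.
#'
#' @param trials trial log.
#' @param include_reversals include reversal-stage rows in the output
#'   (discrimination stages are the headline analysis).
#' @param reversal_stages character vector of stage ids that are
#'   reversals; by default any stage id containing `"rev"`
#'   (case-insensitive).
#' @return Data frame: subject, group, stage_type, prev_valence,
#'   prev_veracity, obey_prob, n_pairs. Cells with no pairs are absent.
#' @export
obey_analysis <- function(trials, include_reversals = FALSE,
                          reversal_stages = NULL) {
  trials <- validate_trials(trials)
  if (is.null(reversal_stages))
    reversal_stages <- unique(grep("rev", trials$stage, ignore.case = TRUE,
                                   value = TRUE))
  n <- nrow(trials)
  if (n < 2L) stop("need at least two trials")
  prev <- seq_len(n - 1L); cur <- prev + 1L
  same <- trials$subject[cur] == trials$subject[prev] &
    trials$stage[cur] == trials$stage[prev] &
    trials$session[cur] == trials$session[prev]
  prev <- prev[same]; cur <- cur[same]
  if (!length(prev)) stop("no within-session trial pairs")
  stayed <- trials$choice_stim[cur] == trials$choice_stim[prev]
  obeyed <- ifelse(trials$outcome[prev] == "reward", stayed, !stayed)
  d <- data.frame(
    subject = trials$subject[prev], group = trials$group[prev],
    stage_type = ifelse(trials$stage[prev] %in% reversal_stages,
                        "reversal", "discrimination"),
    prev_valence = trials$outcome[prev],
    prev_veracity = trials$veracity[prev], obeyed = obeyed,
    stringsAsFactors = FALSE)
  if (!include_reversals)
    d <- d[d$stage_type == "discrimination", , drop = FALSE]
  if (!nrow(d)) stop("no pairs left after stage-type filtering")
  agg <- aggregate(obeyed ~ subject + group + stage_type + prev_valence +
                     prev_veracity, data = d, FUN = mean)
  cnt <- aggregate(obeyed ~ subject + group + stage_type + prev_valence +
                     prev_veracity, data = d, FUN = length)
  names(agg)[names(agg) == "obeyed"] <- "obey_prob"
  agg$n_pairs <- cnt$obeyed
  agg <- agg[order(agg$subject, agg$stage_type, agg$prev_valence,
                   agg$prev_veracity), ]
  rownames(agg) <- NULL
  agg
}

#' Write an obey table or errors table as tab-separated text
#'
#' @param x a data frame from [obey_analysis()] or
#'   [errors_to_criterion()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
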