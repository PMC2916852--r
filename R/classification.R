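#' Classify one subject's decision strategy
#'
#' The winning strategy is the one with the maximal log-likelihood; the
#' margin is the gap to the runner-up (natural-log units, the scale on which
#' a margin of 3 is conventionally read as substantial evidence). A subject
#' is included under a margin criterion iff the margin exceeds the
#' threshold; exact ties are flagged and excluded.
#'
#' @param fits Named list of [fit_strategy()] results (>= 2 strategies).
#' @param margin_threshold Inclusion threshold on the log-likelihood margin
#'   (default 3).
#' @param subject Optional subject id carried into the result.
#' @param n_responses Response count used for BIC (taken from the fits if
#'   omitted).
#' @return An object of class `"classification_result"`: list with
#'   `subject`, `logliks`, `winner`, `margin`, `included`, `tie`, `bic`
#'   (named vector), `margin_threshold`.
#' @export
classify_subject <- function(fits, margin_threshold = 3, subject = NA,
                             n_responses = NULL) {
  if (length(fits) < 2) stop("need at least two strategy fits to classify")
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  nms <- vapply(fits, function(f)
    if (is.null(f$strategy)) NA_character_ else f$strategy, character(1))
  # label by each fit's strategy; fall back to list names when ambiguous
  # (e.g. biased selection competing alongside standard selection)
  if (anyNA(nms) || anyDuplicated(nms)) nms <- names(ll)
  names(ll) <- nms
  ord <- order(ll, decreasing = TRUE)
  margin <- ll[ord[1]] - ll[ord[2]]
  tie <- margin == 0
  if (is.null(n_responses)) n_responses <- fits[[1]]$n_responses
  bics <- vapply(seq_along(fits), function(i)
    bic(fits[[i]], n_responses), numeric(1))
  names(bics) <- names(ll)
  structure(
    list(subject = subject, logliks = ll,
         winner = if (tie) NA_character_ else names(ll)[ord[1]],
         margin = unname(margin),
         included = !tie && margin > margin_threshold,
         tie = tie, bic = bics, margin_threshold = margin_threshold),
    class = "classification_result")
}

#' Bayesian Information Criterion of a strategy fit
#'
#' `BIC = k log(n) - 2 logLik`, with `k` the number of free parameters (4
#' for the standard strategies, 5 for biased-criterion selection) and `n`
#' the number of responses. Lower is better.
#'
#' @param fit A [fit_strategy()] result (uses its `n_par` and `loglik`).
#' @param n_responses Number of responses entering the likelihood.
#' @return The BIC value.
#' @export
bic <- function(fit, n_responses) {
  stopifnot(n_responses >= 1)
  fit$n_par * log(n_responses) - 2 * fit$loglik
}

#' Cohort-level strategy tabulation
#'
#' Counts and percentages of subjects classified to each strategy under
#' three inclusion regimes: no exclusion, margin > 3, and margin > 10
#' (sensitivity check), plus margin statistics among included subjects.
#'
#' @param results List of [classify_subject()] results.
#' @param thresholds Margin thresholds to tabulate (default `c(0, 3, 10)`;
#'   0 means no exclusion beyond ties).
#' @return A list with `table` (data frame: `threshold`, `strategy`,
#'   `count`, `percent`), `n_included` per threshold, and `margin_stats`
#'   (mean/median margin among subjects passing each threshold).
#' @export
tabulate_cohort <- function(results, thresholds = c(0, 3, 10)) {
  stopifnot(length(results) > 0)
  winners <- vapply(results, function(r)
    ifelse(r$tie, NA_character_, r$winner), character(1))
  margins <- vapply(results, function(r) r$margin, numeric(1))
  strat_levels <- unique(unlist(lapply(results, function(r)
    names(r$logliks))))
  rows <- list(); n_inc <- c(); mstats <- list()
  for (th in thresholds) {
    inc <- !is.na(winners) & margins > th
    n <- sum(inc)
    cnt <- table(factor(winners[inc], levels = strat_levels))
    rows[[as.character(th)]] <- data.frame(
      threshold = th, strategy = strat_levels,
      count = as.integer(cnt),
      percent = if (n > 0) 100 * as.integer(cnt) / n else rep(0, length(cnt)))
    n_inc <- c(n_inc, setNames(n, th))
    mstats[[as.character(th)]] <- c(
      mean = if (n > 0) mean(margins[inc]) else NA_real_,
      median = if (n > 0) median(margins[inc]) else NA_real_)
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       n_included = n_inc,
       margin_stats = do.call(rbind, mstats))
}

#' End-to-end strategy recovery on a synthetic cohort
#'
#' Generates (or takes) a cohort of synthetic observers, fits every
#' candidate strategy to each, classifies them, and compares against the
#' generating strategies: the core validation that the fitting and
#' classification pipeline can recover what generated the data.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [fit_config()].
#' @param margin_threshold Margin criterion used for the filtered accuracy.
#' @param verbose Print one line per subject as fits complete.
#' @return A list of class `"recovery_result"`: `per_subject` data frame
#'   (subject, generating strategy and parameters, winner, margin,
#'   per-strategy logliks, fitted parameters of the generating strategy's
#'   fit, R^2), `confusion` (generating x winner table), `accuracy`
#'   (unfiltered), `accuracy_included` (among margin survivors),
#'   `classifications`, and `fits`.
#' @export
run_recovery <- function(cohort, config = fit_config(),
                         margin_threshold = 3, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  fits_all <- vector("list", length(cohort$subjects))
  class_all <- vector("list", length(cohort$subjects))
  rows <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    dat <- cohort$subjects[[i]]
    spec <- cohort$specs[[i]]
    fits <- fit_subject(dat, config)
    cl <- classify_subject(fits, margin_threshold, subject = spec$subject)
    gen_fit <- fits[[spec$strategy]]
    r2 <- nagelkerke_r2(fits[[cl$winner %||% spec$strategy]],
                        null_loglik(dat, config))
    rows[[i]] <- data.frame(
      subject = spec$subject, generating = spec$strategy,
      winner = cl$winner %||% NA_character_, margin = cl$margin,
      included = cl$included, r2 = r2,
      loglik_averaging = cl$logliks[["averaging"]],
      loglik_selection = cl$logliks[["selection"]],
      loglik_matching = cl$logliks[["matching"]],
      gen_sigma_A = spec$params$sigma_A, gen_sigma_V = spec$params$sigma_V,
      gen_sigma_P = spec$params$sigma_P, gen_p_common = spec$params$p_common,
      fit_sigma_A = gen_fit$params$sigma_A,
      fit_sigma_V = gen_fit$params$sigma_V,
      fit_sigma_P = gen_fit$params$sigma_P,
      fit_p_common = gen_fit$params$p_common)
    fits_all[[i]] <- fits
    class_all[[i]] <- cl
    if (verbose) {
      message(sprintf("%s: generated by %s, winner %s (margin %.1f)",
                      spec$subject, spec$strategy, cl$winner, cl$margin))
    }
  }
  per_subject <- do.call(rbind, rows)
  confusion <- table(generating = per_subject$generating,
                     winner = per_subject$winner)
  acc <- mean(per_subject$winner == per_subject$generating, na.rm = TRUE)
  inc <- per_subject$included
  acc_inc <- if (any(inc)) {
    mean(per_subject$winner[inc] == per_subject$generating[inc])
  } else NA_real_
  structure(list(per_subject = per_subject, confusion = confusion,
                 accuracy = acc, accuracy_included = acc_inc,
                 classifications = class_all, fits = fits_all,
                 config = config, margin_threshold = margin_threshold),
            class = "recovery_result")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "strategy recovery: %d subjects, accuracy %.1f%% (margin > %g survivors: %.1f%%)\n",
    nrow(x$per_subject), 100 * x$accuracy, x$margin_threshold,
    100 * x$accuracy_included))
  print(x$confusion)
  invisible(x)
}
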