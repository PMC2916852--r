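#' Write a subject dataset to CSV
#'
#' Column layout: `subject, trial, cond_type, s_A, s_V, resp_A, resp_V`
#' (degrees, one decimal; empty fields for absent modalities). Provenance
#' (seeds, generating strategy, package version) is written as `#`-prefixed
#' header lines so a dataset can be regenerated exactly.
#'
#' @param data A subject dataset (or several row-bound subjects).
#' @param path Output file.
#' @param provenance Named list written into the header; defaults to the
#'   dataset's `spec` attribute when generated by [generate_subject()].
#' @return `path`, invisibly.
#' @export
write_subject_csv <- function(data, path, provenance = NULL) {
  if (is.null(provenance)) {
    spec <- attr(data, "spec")
    if (!is.null(spec)) {
      provenance <- list(strategy = spec$strategy, seed = spec$seed,
                         sigma_A = spec$params$sigma_A,
                         sigma_V = spec$params$sigma_V,
                         sigma_P = spec$params$sigma_P,
                         p_common = spec$params$p_common)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, format(provenance[[k]])), con)
  }
  out <- data.frame(
    subject = data$subject, trial = data$trial, cond_type = data$cond_type,
    s_A = fmt_deg(data$s_A), s_V = fmt_deg(data$s_V),
    resp_A = fmt_deg(data$resp_A), resp_V = fmt_deg(data$resp_V))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_deg <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

#' Read a subject dataset from CSV
#'
#' Inverse of [write_subject_csv()]. Validates structure: condition types,
#' numeric fields, the modality pattern per condition type (bisensory trials
#' must carry both responses), and reports the offending line and column on
#' failure. Provenance header lines are kept as the `"provenance"`
#' attribute.
#'
#' @param path CSV file written by [write_subject_csv()] (or matching its
#'   layout).
#' @return A `subject_data` data frame.
#' @export
read_subject_csv <- function(path) {
  lines <- readLines(path)
  prov_lines <- grep("^#", lines, value = TRUE)
  raw <- read.csv(text = lines[!grepl("^#", lines)],
                  colClasses = c(subject = "character"),
                  stringsAsFactors = FALSE)
  need <- c("subject", "trial", "cond_type", "s_A", "s_V", "resp_A", "resp_V")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("s_A", "s_V", "resp_A", "resp_V")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(trimws(as.character(raw[[col]]))) &
                   is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data line %d",
                   col, bad[1]))
    }
    raw[[col]] <- v
  }
  bad_type <- which(!raw$cond_type %in% c("A", "V", "AV"))
  if (length(bad_type)) {
    stop(sprintf("invalid cond_type at data line %d (column 'cond_type')",
                 bad_type[1]))
  }
  chk <- function(sel, col, want_na) {
    bad <- which(sel & (is.na(raw[[col]]) != want_na))[1]
    if (!is.na(bad)) {
      stop(sprintf("column '%s' %s at data line %d for cond_type %s",
                   col, if (want_na) "must be empty" else "is missing",
                   bad, raw$cond_type[bad]))
    }
  }
  chk(raw$cond_type == "A", "s_A", FALSE)
  chk(raw$cond_type == "A", "resp_A", FALSE)
  chk(raw$cond_type == "A", "s_V", TRUE)
  chk(raw$cond_type == "V", "s_V", FALSE)
  chk(raw$cond_type == "V", "resp_V", FALSE)
  chk(raw$cond_type == "V", "s_A", TRUE)
  chk(raw$cond_type == "AV", "resp_A", FALSE)
  chk(raw$cond_type == "AV", "resp_V", FALSE)
  structure(raw, class = c("subject_data", "data.frame"),
            provenance = prov_lines)
}

#' Write a fit result (or list of them) as JSON
#'
#' @param fits A [fit_strategy()] result or a named list of them.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  ser <- lapply(fits, function(f) {
    list(strategy = f$strategy, params = unclass(f$params),
         loglik = f$loglik, n_responses = f$n_responses,
         n_par = f$n_par, free_criterion = f$free_criterion,
         n_clipped = f$n_clipped,
         diagnostics = f$diagnostics,
         config = list(mc_samples = f$config$mc_samples,
                       bin_width = f$config$bin_width,
                       prob_floor = f$config$prob_floor,
                       restarts = f$config$restarts,
                       seed = f$config$seed))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-subject classification results as JSON lines
#'
#' @param results List of [classify_subject()] results.
#' @param path Output `.jsonl` file (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_classification_jsonl <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in results) {
    writeLines(jsonlite::toJSON(
      list(subject = r$subject, logliks = as.list(r$logliks),
           winner = r$winner, margin = r$margin, included = r$included,
           tie = r$tie, bic = as.list(r$bic),
           margin_threshold = r$margin_threshold),
      auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Write a cohort strategy table to CSV
#'
#' Mirrors the cohort summary layout (strategy, count, percentage per
#' inclusion regime) with margin statistics in header comments.
#'
#' @param tab A [tabulate_cohort()] result.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (th in rownames(tab$margin_stats)) {
    writeLines(sprintf(
      "# margin > %s: n = %d, mean margin %.2f, median margin %.2f",
      th, tab$n_included[[th]], tab$margin_stats[th, "mean"],
      tab$margin_stats[th, "median"]), con)
  }
  write.csv(tab$table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write binned response distributions to CSV
#'
#' Long format: one row per (condition, modality, bin) with the bin center
#' and probability; condition, strategy, sample count and seed travel in
#' columns so several conditions can share a file.
#'
#' @param dists A [simulate_condition()] result or list of them.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dists, path) {
  if (inherits(dists, "response_distribution")) dists <- list(dists)
  rows <- lapply(dists, function(d) {
    per_mod <- list()
    for (mod in c("A", "V")) {
      p <- if (mod == "A") d$p_A else d$p_V
      if (is.null(p)) next
      keep <- p > 0
      per_mod[[mod]] <- data.frame(
        strategy = d$strategy, s_A = d$condition$s_A, s_V = d$condition$s_V,
        modality = mod, bin_center = d$grid$centers[keep],
        probability = p[keep], n = d$n, seed = d$seed)
    }
    do.call(rbind, per_mod)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Panel plot of simulated response distributions
#'
#' One panel per condition, auditory distribution in blue and visual in
#' magenta, with dotted lines at the true stimulus azimuths — the standard
#' way of eyeballing the unimodal (averaging) vs bimodal
#' (selection/matching) signature.
#'
#' @param dists List of [simulate_condition()] results (e.g. one strategy
#'   across the five discrepancy columns).
#' @param smooth_bandwidth Kernel SD (degrees) applied for display only.
#' @return A ggplot object.
#' @export
plot_response_distributions <- function(dists, smooth_bandwidth = 1.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_response_distributions() requires ggplot2")
  }
  if (inherits(dists, "response_distribution")) dists <- list(dists)
  long <- do.call(rbind, lapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    lab <- sprintf("%s | s_A=%s, s_V=%s", d$strategy,
                   format(d$condition$s_A), format(d$condition$s_V))
    out <- list()
    for (mod in c("A", "V")) {
      p <- if (mod == "A") d$p_A else d$p_V
      if (is.null(p)) next
      out[[mod]] <- data.frame(
        panel = lab, modality = mod, x = d$grid$centers,
        density = kernel_smooth(p, d$grid$bin_width, smooth_bandwidth) /
          d$grid$bin_width,
        s_A = d$condition$s_A, s_V = d$condition$s_V)
    }
    do.call(rbind, out)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$density,
                                     fill = .data$modality)) +
    ggplot2::geom_area(alpha = 0.5, position = "identity") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$s_A),
                        linetype = "dotted", colour = "blue", na.rm = TRUE) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$s_V),
                        linetype = "dotted", colour = "magenta",
                        na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(A = "blue", V = "magenta")) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(xlim = c(-35, 35)) +
    ggplot2::labs(x = "azimuth (deg)", y = "response density") +
    ggplot2::theme_minimal()
}
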