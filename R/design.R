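#' Speaker/flash azimuths of the standard design
#'
#' Five locations spaced 6.5 degrees apart along the azimuth.
#'
#' @return Numeric vector `c(-13, -6.5, 0, 6.5, 13)` (degrees).
#' @export
standard_locations <- function() c(-13, -6.5, 0, 6.5, 13)

#' Build the trial list of the localization experiment
#'
#' The standard session crosses 5 auditory-only conditions, 5 visual-only
#' conditions and all 25 auditory-visual pairings (35 unique conditions),
#' each repeated `repetitions` times and presented in pseudorandom order.
#' With the default 15 repetitions this yields 525 trials.
#'
#' @param repetitions Repetitions per condition (default 15).
#' @param seed Integer seed for the pseudorandom trial order.
#' @param locations Stimulus azimuths, degrees (default
#'   [standard_locations()]).
#' @return A data frame of class `"experiment_design"` with columns `trial`,
#'   `cond_type` (`"A"`, `"V"`, `"AV"`), `s_A`, `s_V` (degrees; `NA` for the
#'   absent modality), and attributes `repetitions`, `locations`, `seed`.
#' @examples
#' d <- build_design(repetitions = 15, seed = 1)
#' nrow(d)                      # 525
#' nrow(unique(d[-1]))          # 35 conditions
#' @export
build_design <- function(repetitions = 15, seed = 1,
                         locations = standard_locations()) {
  stopifnot(repetitions >= 1)
  conds <- rbind(
    data.frame(cond_type = "A", s_A = locations, s_V = NA_real_),
    data.frame(cond_type = "V", s_A = NA_real_, s_V = locations),
    expand.grid(cond_type = "AV", s_A = locations, s_V = locations,
                stringsAsFactors = FALSE)[, c("cond_type", "s_A", "s_V")])
  trials <- conds[rep(seq_len(nrow(conds)), times = repetitions), ]
  ord <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[ord, ]
  trials <- cbind(trial = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  structure(trials, class = c("experiment_design", "data.frame"),
            repetitions = repetitions, locations = locations, seed = seed)
}

#' Unique conditions of a design or dataset
#'
#' @param trials A data frame with columns `cond_type`, `s_A`, `s_V`.
#' @return A data frame of unique conditions with a `cond_id` column.
#' @export
condition_table <- function(trials) {
  u <- unique(data.frame(cond_type = trials$cond_type,
                         s_A = trials$s_A, s_V = trials$s_V))
  u <- u[order(u$cond_type, u$s_A, u$s_V, na.last = TRUE), ]
  rownames(u) <- NULL
  cbind(cond_id = seq_len(nrow(u)), u)
}

# run code under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
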