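#' Detection-accuracy curves on a surrogate cohort
#'
#' Reproduces the injection-based evaluation protocol: for each magnitude and
#' replicate, fresh noisy baselines are built per participant, a positive
#' change (or habit) is injected at 08:00 and a negative one at noon on day 7
#' (days 7-9 for habits), the detector is run in batch, and detections are
#' matched exactly on (day, hour, sign). A change counts as detected only if
#' a change event of matching sign exists at day 7 and the injected hour; a
#' habit only if a habit event of matching sign starts at day 7 and the
#' injected hour and is sustained through day 9.
#'
#' @param spec A [cohort_spec()].
#' @param magnitudes Injected magnitudes in steps/hour, ascending.
#' @param kind `"change"` or `"habit"`.
#' @param cfg A [detector_config()].
#' @param n_reps Number of independent noise replicates (seeds) per
#'   magnitude.
#' @param seed Integer seed fixing the cohort draw and all baseline noise.
#' @param pos_hour,neg_hour Injection hours for the positive and negative
#'   events.
#' @param paired When `TRUE`, one baseline per (replicate, participant) is
#'   reused across all magnitudes (variance reduction); the default redraws
#'   baseline noise for every magnitude, matching the independent-experiment
#'   framing.
#' @return A tibble with one row per (magnitude, sign): columns `group`,
#'   `event_kind`, `sign`, `magnitude`, `n`, `detected`, `accuracy`.
#' @export
evaluate_accuracy <- function(spec, magnitudes, kind = c("change", "habit"),
                              cfg = detector_config(), n_reps = 10, seed = NULL,
                              pos_hour = 8, neg_hour = 12, paired = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  kind <- match.arg(kind)
  if (is.unsorted(magnitudes)) stop("`magnitudes` must be ascending", call. = FALSE)
  if (spec$n_days < 9L) stop("the evaluation design needs at least 9 days", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(spec)
  n_p <- length(cohort)
  inj_days <- if (kind == "change") 7L else 7:9
  det_day_idx <- 7L
  end_day_idx <- 9L

  det_pos <- det_neg <- stats::setNames(rep(0L, length(magnitudes)),
                                        as.character(magnitudes))
  for (rep_i in seq_len(n_reps)) {
    base_set <- if (paired) lapply(cohort, build_baseline, n_days = spec$n_days)
    for (mi in seq_along(magnitudes)) {
      m <- magnitudes[mi]
      for (p in seq_len(n_p)) {
        base <- if (paired) base_set[[p]] else build_baseline(cohort[[p]], spec$n_days)
        si <- inject_steps(base, injection_spec(kind, "add", m, pos_hour, inj_days))
        si <- inject_steps(si, injection_spec(kind, "remove", m, neg_hour, inj_days))
        res <- detect_batch(si, cfg)
        d7 <- base$days[det_day_idx]
        d9 <- base$days[end_day_idx]
        if (kind == "change") {
          hit_pos <- any(res$changes$day == d7 & res$changes$hour == pos_hour &
                           res$changes$type == "Positive")
          hit_neg <- any(res$changes$day == d7 & res$changes$hour == neg_hour &
                           res$changes$type == "Negative")
        } else {
          hit_pos <- any(res$habits$first_day == d7 & res$habits$hour == pos_hour &
                           res$habits$last_day == d9 & res$habits$type == "Positive")
          hit_neg <- any(res$habits$first_day == d7 & res$habits$hour == neg_hour &
                           res$habits$last_day == d9 & res$habits$type == "Negative")
        }
        det_pos[mi] <- det_pos[mi] + hit_pos
        det_neg[mi] <- det_neg[mi] + hit_neg
      }
    }
  }
  n_inj <- n_p * n_reps
  tibble::tibble(
    group = spec$group,
    event_kind = kind,
    sign = rep(c("positive", "negative"), each = length(magnitudes)),
    magnitude = rep(as.numeric(magnitudes), 2L),
    n = n_inj,
    detected = c(unname(det_pos), unname(det_neg)),
    accuracy = c(unname(det_pos), unname(det_neg)) / n_inj
  )
}

#' Baseline false-positive rate
#'
#' Runs the detector over uninjected baselines and reports the fraction of
#' participant-hours flagged as behaviour changes. The baselines are built to
#' contain no behaviour changes, so this automated sweep plays the role of a
#' manual inspection of the simulated dataset: any flagged hour is a false
#' positive of the noise model.
#'
#' @inheritParams evaluate_accuracy
#' @return A single fraction in `[0, 1]`.
#' @export
baseline_false_positive_rate <- function(spec, cfg = detector_config(),
                                         n_reps = 1, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(spec)
  flagged <- 0L
  total <- 0L
  for (rep_i in seq_len(n_reps)) {
    for (p in seq_along(cohort)) {
      base <- build_baseline(cohort[[p]], spec$n_days)
      res <- detect_batch(base, cfg)
      flagged <- flagged + nrow(res$changes)
      total <- total + length(base$values)
    }
  }
  if (total == 0L) return(0)
  flagged / total
}
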