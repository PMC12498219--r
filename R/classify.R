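#' Published normative VOR-gain ranges
#'
#' Mean +/- 2 SD reference intervals from 18 healthy age- and sex-matched
#' controls, shipped as frozen constants: HC 0.86-1.20, AC 0.74-1.23,
#' PC 0.72-1.29. Use [build_normative_range()] to derive ranges from a new
#' control cohort instead.
#'
#' @return data.frame with columns `canal_class`, `low`, `high`, `source`.
#' @export
default_normative_ranges <- function() {
  data.frame(
    canal_class = CANALS,
    low = c(0.86, 0.74, 0.72),
    high = c(1.20, 1.23, 1.29),
    source = "fixed_published"
  )
}

#' Derive a normative range from control gains
#'
#' The reference range is `mean(control_gains) +/- 2 * SD` with the sample
#' (n - 1) standard deviation.
#'
#' @param control_gains numeric vector of control VOR gains (length >= 2).
#' @param canal_class `"HC"`, `"AC"` or `"PC"`.
#' @return one-row data.frame matching [default_normative_ranges()].
#' @export
build_normative_range <- function(control_gains, canal_class = "HC") {
  if (length(control_gains) < 2L) {
    stop_input("need at least 2 control gains to derive a normative range")
  }
  s <- stats::sd(control_gains)
  if (s == 0) warning("control gains are constant; normative range is degenerate")
  m <- mean(control_gains)
  data.frame(canal_class = canal_class, low = m - 2 * s, high = m + 2 * s,
             source = "derived_from_controls")
}

#' Classify a canal gain against its normative range
#'
#' Bounds are inclusive: a gain exactly at a bound is normal; only gains
#' strictly outside the range are abnormal (`"decreased"` below,
#' `"overestimated"` above). Missing gains yield `"unavailable"`.
#'
#' @param gain numeric vector of mean VOR gains (NA allowed).
#' @param canal_class `"HC"`, `"AC"` or `"PC"` (recycled).
#' @param ranges normative ranges table; default [default_normative_ranges()].
#' @return character vector of statuses.
#' @export
canal_status <- function(gain, canal_class, ranges = default_normative_ranges()) {
  k <- match(canal_class, ranges$canal_class)
  if (anyNA(k)) stop_input("unknown canal_class in `canal_class`")
  low <- ranges$low[k]
  high <- ranges$high[k]
  out <- ifelse(is.na(gain), "unavailable",
                ifelse(gain < low, "decreased",
                       ifelse(gain > high, "overestimated", "normal")))
  as.character(out)
}

# side pattern from two logical flags (right, left)
side_pattern <- function(right, left) {
  if (right && left) "both" else if (right) "right_only" else if (left) "left_only" else "none"
}

#' Patient-level VOR pattern from six canal statuses
#'
#' @param statuses named character vector of six statuses with names
#'   `rhc, lhc, rac, lac, rpc, lpc` (as produced by [canal_status()]).
#' @return list with `any_decreased`, `any_overestimated`, `all_normal`, and
#'   per-canal-class side patterns `decreased` / `overestimated` (each a named
#'   character vector over HC/AC/PC with values
#'   `right_only`/`left_only`/`both`/`none`).
#' @export
patient_pattern <- function(statuses) {
  need <- c("rhc", "lhc", "rac", "lac", "rpc", "lpc")
  if (!all(need %in% names(statuses))) {
    stop_input("statuses must be named rhc, lhc, rac, lac, rpc, lpc")
  }
  pat <- function(category) {
    out <- vapply(CANALS, function(cc) {
      r <- statuses[[paste0("r", tolower(cc))]] == category
      l <- statuses[[paste0("l", tolower(cc))]] == category
      side_pattern(r, l)
    }, character(1))
    stats::setNames(out, CANALS)
  }
  dec <- pat("decreased")
  ove <- pat("overestimated")
  any_dec <- any(dec != "none")
  any_ove <- any(ove != "none")
  list(any_decreased = any_dec, any_overestimated = any_ove,
       all_normal = !any_dec && !any_ove,
       decreased = dec, overestimated = ove)
}

#' Classify an RCFT score
#'
#' A Rey Complex Figure test domain (copying or delayed recall) is abnormal
#' when its age/education-standardised z-score is strictly below the
#' threshold: -2.0 for the primary rule, -1.0 for the sensitivity rule.
#'
#' @param z numeric vector of z-scores (NA allowed).
#' @param threshold abnormality threshold in z units (default -2.0).
#' @param domain `"copying"` or `"delayed_recall"` (label only).
#' @return data.frame with columns `domain`, `abnormal` (logical, NA when z
#'   missing), `threshold`.
#' @export
rcft_status <- function(z, threshold = -2.0, domain = "copying") {
  data.frame(domain = domain, abnormal = ifelse(is.na(z), NA, z < threshold),
             threshold = threshold)
}

#' Cohort-level pattern counts
#'
#' Aggregates per-patient canal statuses and RCFT classifications into the
#' counts reported for a vHIT cohort: number of all-normal patients, per
#' canal class and category (decreased / overestimated) the right-only /
#' left-only / both-sides breakdown and total, the any-decreased /
#' any-overestimated / both-categories patient counts, and abnormal RCFT
#' counts. Percentages are of the cohort size, rounded half away from zero
#' to integers.
#'
#' @param cohort data.frame with the six gain columns
#'   `gain_rhc, gain_lhc, gain_rac, gain_lac, gain_rpc, gain_lpc` and
#'   (optionally) `rcft_copy_z`, `rcft_recall_z`.
#' @param ranges normative ranges table.
#' @param rcft_threshold z threshold for RCFT abnormality.
#' @return nested list of counts and percentages (class `cohort_counts`).
#' @export
cohort_counts <- function(cohort, ranges = default_normative_ranges(),
                          rcft_threshold = -2.0) {
  if (!nrow(cohort)) stop_input("empty cohort")
  miss <- setdiff(GAIN_COLS, names(cohort))
  if (length(miss)) {
    stop_input("cohort lacks gain columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(cohort)
  pats <- lapply(seq_len(n), function(i) {
    st <- vapply(GAIN_COLS, function(col) {
      cc <- toupper(substr(sub("gain_", "", col), 2, 3))
      canal_status(cohort[[col]][i], cc, ranges)
    }, character(1))
    names(st) <- sub("gain_", "", GAIN_COLS)
    patient_pattern(st)
  })
  pct <- function(k) as.integer(round_half_up(100 * k / n))
  per_class <- function(category) {
    out <- lapply(CANALS, function(cc) {
      p <- vapply(pats, function(x) x[[category]][[cc]], character(1))
      counts <- list(
        right_only = sum(p == "right_only"),
        left_only = sum(p == "left_only"),
        both = sum(p == "both")
      )
      counts$total <- counts$right_only + counts$left_only + counts$both
      counts
    })
    stats::setNames(out, CANALS)
  }
  any_dec <- vapply(pats, `[[`, logical(1), "any_decreased")
  any_ove <- vapply(pats, `[[`, logical(1), "any_overestimated")
  all_norm <- vapply(pats, `[[`, logical(1), "all_normal")

  res <- list(
    n = n,
    n_all_normal = sum(all_norm), pct_all_normal = pct(sum(all_norm)),
    decreased = per_class("decreased"),
    overestimated = per_class("overestimated"),
    n_any_decreased = sum(any_dec),
    n_any_overestimated = sum(any_ove),
    pct_any_overestimated = pct(sum(any_ove)),
    n_both_categories = sum(any_dec & any_ove)
  )
  if ("rcft_copy_z" %in% names(cohort)) {
    k <- sum(rcft_status(cohort$rcft_copy_z, rcft_threshold)$abnormal, na.rm = TRUE)
    res$n_abnormal_copy <- k
    res$pct_abnormal_copy <- pct(k)
  }
  if ("rcft_recall_z" %in% names(cohort)) {
    k <- sum(rcft_status(cohort$rcft_recall_z, rcft_threshold,
                         domain = "delayed_recall")$abnormal, na.rm = TRUE)
    res$n_abnormal_recall <- k
    res$pct_abnormal_recall <- pct(k)
  }
  structure(res, class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("vHIT cohort of %d patients\n", x$n))
  cat(sprintf("  VOR gain normal in %d (%d%%)\n", x$n_all_normal, x$pct_all_normal))
  for (cat_name in c("decreased", "overestimated")) {
    tot_n <- if (cat_name == "decreased") x$n_any_decreased else x$n_any_overestimated
    cat(sprintf("  %s gain for >= 1 canal: %d patients\n", cat_name, tot_n))
    for (cc in CANALS) {
      k <- x[[cat_name]][[cc]]
      cat(sprintf("    %s: %d (right only %d; left only %d; both %d)\n",
                  cc, k$total, k$right_only, k$left_only, k$both))
    }
  }
  cat(sprintf("  both categories: %d\n", x$n_both_categories))
  if (!is.null(x$n_abnormal_copy)) {
    cat(sprintf("  abnormal RCFT-copying: %d (%d%%)\n",
                x$n_abnormal_copy, x$pct_abnormal_copy))
  }
  if (!is.null(x$n_abnormal_recall)) {
    cat(sprintf("  abnormal RCFT-delayed recall: %d (%d%%)\n",
                x$n_abnormal_recall, x$pct_abnormal_recall))
  }
  invisible(x)
}
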