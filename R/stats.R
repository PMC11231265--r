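# Validation statistics: 2x2 diagnostic metrics against a reference method,
# dilution-series LOD analysis, replicate reproducibility, cohort summaries.

#' Build a 2x2 concordance table against a reference method
#'
#' @param data Data frame with one row per sample and positive/negative status
#'   under both methods.
#' @param ngs,reference Column names (strings) holding the NGS and
#'   reference-method status; values must be `"positive"` or `"negative"`.
#' @return A `kd_concordance` one-row tibble: `a` (both positive), `b`
#'   (NGS+/ref-), `c` (NGS-/ref+), `d` (both negative), `n`.
#' @examples
#' labels <- validation_labels()
#' concordance_table(labels)
#' @export
concordance_table <- function(data, ngs = "ngs", reference = "reference") {
  for (col in c(ngs, reference)) {
    if (!col %in% names(data)) {
      abort_abl1kd(paste0("missing column: ", col), "abl1kd_validation_error")
    }
  }
  x <- data[[ngs]]
  y <- data[[reference]]
  if (any(is.na(x)) || any(is.na(y))) {
    abort_abl1kd("both methods must label every sample", "abl1kd_validation_error")
  }
  bad <- !(x %in% c("positive", "negative")) | !(y %in% c("positive", "negative"))
  if (any(bad)) {
    abort_abl1kd("status values must be 'positive' or 'negative'",
                 "abl1kd_validation_error")
  }
  out <- tibble(
    a = sum(x == "positive" & y == "positive"),
    b = sum(x == "positive" & y == "negative"),
    c = sum(x == "negative" & y == "positive"),
    d = sum(x == "negative" & y == "negative"),
    n = length(x)
  )
  structure(out, class = c("kd_concordance", class(out)))
}

#' The packaged 21-sample validation label sheet
#'
#' Per-sample NGS and Sanger (reference) statuses of the assay's validation
#' set: 7 concordant positives, 13 concordant negatives, and one NGS-only
#' positive (the 3.85% L298R call, below Sanger's detection limit).
#'
#' @param path Optional TSV path; defaults to the packaged sheet.
#' @return Tibble with `sample_id`, `ngs`, `reference`, `note`.
#' @export
validation_labels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "validation_labels.tsv", package = "abl1kd")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Diagnostic metrics from a 2x2 concordance table
#'
#' Computes sensitivity `100a/(a+c)`, specificity `100d/(b+d)`, PPV
#' `100a/(a+b)`, NPV `100d/(c+d)` and overall concordance `100(a+d)/n` at full
#' precision, plus a rendering under the chosen convention (see
#' [render_percent()]). A metric whose denominator is zero is `NA`
#' ("undefined"), never 0.
#'
#' @param ct A `kd_concordance` (or any one-row data frame with `a,b,c,d`).
#' @param rounding Rendering convention for the `rendered` column.
#' @return A `kd_diagnostics` tibble: `metric`, `numerator`, `denominator`,
#'   `value` (full precision), `rendered`.
#' @examples
#' ct <- concordance_table(validation_labels())
#' diagnostic_metrics(ct)
#' @export
diagnostic_metrics <- function(ct, rounding = c("half_up_2dp", "truncate_2dp", "integer")) {
  rounding <- arg_match(rounding)
  a <- ct$a[1]; b <- ct$b[1]; c <- ct$c[1]; d <- ct$d[1]
  if (any(c(a, b, c, d) < 0)) {
    abort_abl1kd("2x2 cells must be non-negative", "abl1kd_validation_error")
  }
  n <- a + b + c + d
  if (n < 1) abort_abl1kd("empty 2x2 table", "abl1kd_validation_error")
  num <- c(sensitivity = a, specificity = d, ppv = a, npv = d, concordance = a + d)
  den <- c(sensitivity = a + c, specificity = b + d, ppv = a + b, npv = c + d,
           concordance = n)
  value <- ifelse(den > 0, 100 * num / den, NA_real_)
  out <- tibble(
    metric = names(num),
    numerator = unname(num),
    denominator = unname(den),
    value = unname(value),
    rendered = render_percent(unname(value), rounding)
  )
  structure(out, class = c("kd_diagnostics", class(out)),
            table = tibble(a = a, b = b, c = c, d = d, n = n),
            rounding = rounding)
}

#' @method tidy kd_diagnostics
#' @export
tidy.kd_diagnostics <- function(x, ...) as_tibble(x)

#' @method glance kd_diagnostics
#' @export
glance.kd_diagnostics <- function(x, ...) {
  wide <- as.list(setNames(x$value, x$metric))
  as_tibble(c(attr(x, "table")[1, ], wide))
}

#' Expected VAFs along a 1:1 serial dilution
#'
#' @param initial_vaf Undiluted VAF in percent (> 0).
#' @param n_dilutions Number of 1:1 dilution steps (>= 0).
#' @return Numeric vector: element k is `initial_vaf / 2^k`, k = 1..n.
#' @examples
#' expected_dilution_vafs(11.83, 3)
#' render_percent(expected_dilution_vafs(11.83, 3), "half_up_2dp")
#' @export
expected_dilution_vafs <- function(initial_vaf, n_dilutions) {
  if (initial_vaf <= 0) {
    abort_abl1kd("initial_vaf must be > 0", "abl1kd_validation_error")
  }
  if (n_dilutions < 0) {
    abort_abl1kd("n_dilutions must be >= 0", "abl1kd_validation_error")
  }
  if (n_dilutions == 0) return(numeric(0))
  initial_vaf / 2^seq_len(n_dilutions)
}

#' Dilution-series LOD analysis
#'
#' Pairs the expected (halving) series with the observed VAFs, reports deltas,
#' and estimates the limit of detection as the smallest observed VAF among
#' detected steps (`NA` when nothing was detected). The declared assay LOD
#' stays a calling parameter ([call_params()]), not an output of this
#' analysis.
#'
#' @param expected Expected VAF series (percent), e.g. from
#'   [expected_dilution_vafs()].
#' @param observed Observed VAF series (percent), same length.
#' @param detected Logical detection flags per step (default: all `TRUE`).
#' @param initial_vaf Optional undiluted VAF, carried into the result.
#' @return A `kd_dilution` tibble (`step`, `expected`, `observed`, `delta`,
#'   `detected`) with attributes `lod_estimate` and `initial_vaf`.
#' @examples
#' da <- dilution_analysis(expected_dilution_vafs(11.83, 3), c(3.91, 2.78, 2.32))
#' attr(da, "lod_estimate")
#' @export
dilution_analysis <- function(expected, observed, detected = rep(TRUE, length(observed)),
                              initial_vaf = NA_real_) {
  if (length(expected) != length(observed) || length(observed) != length(detected)) {
    abort_abl1kd("expected, observed and detected must have equal length",
                 "abl1kd_validation_error")
  }
  lod <- if (any(detected)) min(observed[detected]) else NA_real_
  out <- tibble(
    step = seq_along(expected),
    expected = expected,
    observed = observed,
    delta = observed - expected,
    detected = detected
  )
  structure(out, class = c("kd_dilution", class(out)),
            lod_estimate = lod, initial_vaf = initial_vaf)
}

#' @method tidy kd_dilution
#' @export
tidy.kd_dilution <- function(x, ...) as_tibble(x)

#' @method glance kd_dilution
#' @export
glance.kd_dilution <- function(x, ...) {
  tibble(
    n_steps = nrow(x),
    n_detected = sum(x$detected),
    lod_estimate = attr(x, "lod_estimate"),
    initial_vaf = attr(x, "initial_vaf")
  )
}

#' Replicate reproducibility statistics
#'
#' Computes per-variant absolute VAF differences between two runs, an ordinary
#' least-squares regression of run 2 on run 1 (slope, intercept, R²; `NA` with
#' fewer than 2 pairs), and — when sample-level statuses are supplied — the
#' qualitative positive/negative concordance fraction.
#'
#' @param pairs Data frame with columns `vaf_run1` and `vaf_run2` (optionally
#'   `variant`).
#' @param status Optional data frame with columns `status_run1`, `status_run2`
#'   (values `"positive"`/`"negative"`, one row per sample).
#' @return A `kd_repro` tibble (the pairs with `abs_diff`) with attributes
#'   `slope`, `intercept`, `r_squared`, `concordance_pct`.
#' @examples
#' reproducibility_stats(replicate_pairs())
#' @export
reproducibility_stats <- function(pairs, status = NULL) {
  stopifnot(all(c("vaf_run1", "vaf_run2") %in% names(pairs)))
  out <- mutate(as_tibble(pairs), abs_diff = abs(.data$vaf_run2 - .data$vaf_run1))
  if (nrow(pairs) >= 2) {
    fit <- lm(vaf_run2 ~ vaf_run1, data = pairs)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    # computed directly so an exact fit gives r2 = 1 without lm's
    # perfect-fit caveat
    sst <- sum((pairs$vaf_run2 - mean(pairs$vaf_run2))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  } else {
    slope <- intercept <- r2 <- NA_real_
  }
  conc <- if (!is.null(status)) {
    100 * mean(status$status_run1 == status$status_run2)
  } else NA_real_
  structure(out, class = c("kd_repro", class(out)),
            slope = slope, intercept = intercept, r_squared = r2,
            concordance_pct = conc)
}

#' The packaged replicate-pair sheet
#'
#' VAF pairs of the three positive samples run as two independent libraries
#' (78.86/80.25, 4.17/2.31, 60.77/56.14) plus the two concordant negative
#' samples' statuses.
#'
#' @param path Optional TSV path; defaults to the packaged sheet.
#' @return Tibble with `sample_id`, `variant`, `vaf_run1`, `vaf_run2`,
#'   `status_run1`, `status_run2`.
#' @export
replicate_pairs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "replicate_pairs.tsv", package = "abl1kd")
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), variant = readr::col_character(),
    vaf_run1 = readr::col_double(), vaf_run2 = readr::col_double(),
    status_run1 = readr::col_character(), status_run2 = readr::col_character()
  ))
}

#' @method tidy kd_repro
#' @export
tidy.kd_repro <- function(x, ...) as_tibble(x)

#' @method glance kd_repro
#' @export
glance.kd_repro <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    slope = attr(x, "slope"),
    intercept = attr(x, "intercept"),
    r_squared = attr(x, "r_squared"),
    mean_abs_diff = mean(x$abs_diff),
    concordance_pct = attr(x, "concordance_pct")
  )
}

#' Cohort-level mutation-spectrum summary
#'
#' @param reports List of `kd_sample_report` (e.g. from [reports_from_truth()]
#'   or per-sample pipeline runs).
#' @return A `kd_cohort` list: `n_samples`, `n_positive`, `positivity_pct`,
#'   `n_negative`, `negativity_pct`, `n_variants_total`, `spectrum` (tibble
#'   `protein_change`, `n`, `pct` of total variants), `n_compound`,
#'   `compound_pct_of_positive`, `vaf_min`, `vaf_max`.
#' @examples
#' reports <- reports_from_truth(default_cohort_spec())
#' cohort_summary(reports)
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0) {
    abort_abl1kd("cohort_summary() needs at least one sample report",
                 "abl1kd_validation_error")
  }
  gl <- bind_rows(lapply(reports, glance))
  calls <- bind_rows(lapply(reports, tidy))
  n_samples <- nrow(gl)
  n_positive <- sum(gl$classification != "negative")
  n_compound <- sum(gl$classification == "compound")
  spectrum <- if (nrow(calls) > 0) {
    calls |>
      count(.data$protein_change, sort = TRUE, name = "n") |>
      mutate(pct = 100 * .data$n / sum(.data$n))
  } else {
    tibble(protein_change = character(), n = integer(), pct = numeric())
  }
  structure(
    list(
      n_samples = n_samples,
      n_positive = n_positive,
      positivity_pct = 100 * n_positive / n_samples,
      n_negative = n_samples - n_positive,
      negativity_pct = 100 * (n_samples - n_positive) / n_samples,
      n_variants_total = nrow(calls),
      spectrum = spectrum,
      n_compound = n_compound,
      compound_pct_of_positive = if (n_positive > 0) 100 * n_compound / n_positive else NA_real_,
      vaf_min = if (nrow(calls)) min(calls$vaf) else NA_real_,
      vaf_max = if (nrow(calls)) max(calls$vaf) else NA_real_
    ),
    class = "kd_cohort"
  )
}

#' @export
print.kd_cohort <- function(x, ...) {
  cat(sprintf(
    "Cohort: %d samples; %d positive (%.2f%%), %d negative (%.2f%%)\n",
    x$n_samples, x$n_positive, render_percent(x$positivity_pct, "half_up_2dp"),
    x$n_negative, render_percent(x$negativity_pct, "half_up_2dp")
  ))
  cat(sprintf("%d variants (VAF %.2f-%.2f%%); %d compound samples (%.2f%% of positives)\n",
              x$n_variants_total, x$vaf_min, x$vaf_max, x$n_compound,
              render_percent(x$compound_pct_of_positive, "half_up_2dp")))
  print(head(x$spectrum, 10))
  invisible(x)
}

#' @method tidy kd_cohort
#' @export
tidy.kd_cohort <- function(x, ...) x$spectrum

#' @method glance kd_cohort
#' @export
glance.kd_cohort <- function(x, ...) {
  tibble(
    n_samples = x$n_samples, n_positive = x$n_positive,
    positivity_pct = x$positivity_pct, n_negative = x$n_negative,
    negativity_pct = x$negativity_pct, n_variants_total = x$n_variants_total,
    n_compound = x$n_compound,
    compound_pct_of_positive = x$compound_pct_of_positive,
    vaf_min = x$vaf_min, vaf_max = x$vaf_max
  )
}
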