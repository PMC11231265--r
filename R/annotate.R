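# Annotation: per-variant TKI poor-sensitivity profiles, sample-level TKI
# union, and single/compound classification into clinical-style reports.

#' Annotate one protein change against the hotspot catalogue
#'
#' Exact-match lookup on (wt, codon, mut). Changes absent from the catalogue
#' are still reported — with an empty TKI profile and `in_catalogue = FALSE` —
#' because novel low-VAF variants (e.g. L298R) are clinically relevant even
#' without a curated resistance profile.
#'
#' @param protein_change Character vector of protein-change strings.
#' @param catalogue A `kd_catalogue`.
#' @return Tibble with `protein_change`, `in_catalogue`, one logical column
#'   per TKI, and `poorly_sensitive_tkis` (semicolon-joined, `""` when empty).
#' @examples
#' annotate_variant(c("T315I", "T315M", "L298R"))
#' @export
annotate_variant <- function(protein_change, catalogue = hotspot_catalogue()) {
  canon <- parse_hotspot_notation(protein_change)$protein_change
  i <- match(canon, catalogue$protein_change)
  out <- tibble(
    protein_change = canon,
    in_catalogue = !is.na(i)
  )
  for (t in TKIS) {
    out[[t]] <- ifelse(is.na(i), FALSE, catalogue[[t]][i])
  }
  out$poorly_sensitive_tkis <- vapply(seq_along(i), function(j) {
    if (is.na(i[j])) "" else catalogue$tkis[i[j]]
  }, character(1))
  out
}

#' Annotate a call table with TKI profiles
#'
#' @param calls A `kd_calls` tibble (needs a `protein_change` column).
#' @param catalogue A `kd_catalogue`.
#' @return `calls` with the [annotate_variant()] columns joined on.
#' @export
annotate_calls <- function(calls, catalogue = hotspot_catalogue()) {
  if (nrow(calls) == 0) {
    out <- calls
    for (t in TKIS) out[[t]] <- logical(0)
    out$poorly_sensitive_tkis <- character(0)
    return(out)
  }
  prof <- annotate_variant(calls$protein_change, catalogue)
  bind_cols(calls, prof[, c(TKIS, "poorly_sensitive_tkis")])
}

#' Classify a sample from its passing calls
#'
#' Classification follows the assay's operational usage: `negative` with no
#' passing calls, `single` with one, `compound` with two or more mutations in
#' the same sample (cis/trans phasing is not attempted, so "compound" may
#' include polyclonal configurations). The sample TKI union is the union of
#' the member profiles.
#'
#' @param calls Passing calls only (a `kd_calls` tibble).
#' @param catalogue A `kd_catalogue`.
#' @param qc Optional one-row `kd_qc` tibble.
#' @param sample_id Sample identifier.
#' @return A `kd_sample_report` list: `sample_id`, `qc`, `calls` (annotated,
#'   descending VAF), `classification`, `tki_union` (character vector).
#' @examples
#' # a compound sample: T315I + F359V
#' ref <- build_surrogate_reference(seed = 1)
#' panel <- build_amplicon_panel(ref, seed = 1)
#' sim <- simulate_sample(panel, spike_spec(c("T315I", "F359V"), c(17.76, 63.43)),
#'                        sim_config(reads_total = 6000, seed = 2))
#' res <- call_sample(sim$reads, panel, thresholds = qc_thresholds(100))
#' classify_sample(res$calls, qc = res$qc, sample_id = "sample1")
#' @export
classify_sample <- function(calls, catalogue = hotspot_catalogue(), qc = NULL,
                            sample_id = "sample") {
  if (nrow(calls) > 0 && !all(calls$passes_lod)) {
    abort_abl1kd("classify_sample() expects passing calls only",
                 "abl1kd_validation_error")
  }
  calls <- annotate_calls(arrange(calls, desc(.data$vaf)), catalogue)
  n <- nrow(calls)
  classification <- if (n == 0) "negative" else if (n == 1) "single" else "compound"
  tki_union <- TKIS[vapply(TKIS, function(t) any(calls[[t]]), logical(1))]
  structure(
    list(sample_id = sample_id, qc = qc, calls = calls,
         classification = classification, tki_union = tki_union),
    class = "kd_sample_report"
  )
}

#' @export
print.kd_sample_report <- function(x, ...) {
  cat("Sample ", x$sample_id, ": ", x$classification, sep = "")
  if (x$classification == "negative") {
    cat(" — no KD mutation detected\n")
  } else {
    cat(" (", nrow(x$calls), " variant(s); poorly sensitive to: ",
        if (length(x$tki_union)) paste(x$tki_union, collapse = ", ") else "none listed",
        ")\n", sep = "")
    print(as_tibble(x$calls)[, c("protein_change", "vaf", "depth", "alt_count",
                                 "in_catalogue", "poorly_sensitive_tkis")])
  }
  invisible(x)
}

#' Render a sample report to TSV and JSON
#'
#' The TSV carries one row per variant (negative samples get one explicit
#' "no KD mutation detected" row) plus a sample-level union row; the JSON is a
#' lossless machine-readable form that [read_sample_report()] restores.
#'
#' @param report A `kd_sample_report`.
#' @param dir Output directory; files are named `<sample_id>.report.tsv` and
#'   `<sample_id>.report.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(report$sample_id, ".report"))
  tsv <- paste0(base, ".tsv")
  json <- paste0(base, ".json")

  rows <- report_tsv_rows(report)
  readr::write_tsv(rows, tsv)

  payload <- list(
    sample_id = report$sample_id,
    classification = report$classification,
    tki_union = as.list(report$tki_union),
    qc = if (is.null(report$qc)) NULL else as.list(as_tibble(report$qc)[1, ]),
    calls = as_tibble(report$calls)
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(tsv = tsv, json = json))
}

report_tsv_rows <- function(report) {
  flag <- function(x) ifelse(x, "poor", "")
  if (nrow(report$calls) == 0) {
    variant_rows <- tibble(
      sample = report$sample_id, row_type = "variant",
      variant = "no KD mutation detected", vaf = NA_real_, depth = NA_real_,
      hotspot = NA, I = "", D = "", N = "", B = "", P = ""
    )
  } else {
    variant_rows <- tibble(
      sample = report$sample_id, row_type = "variant",
      variant = report$calls$protein_change,
      vaf = report$calls$vaf, depth = report$calls$depth,
      hotspot = report$calls$in_catalogue,
      I = flag(report$calls$imatinib), D = flag(report$calls$dasatinib),
      N = flag(report$calls$nilotinib), B = flag(report$calls$bosutinib),
      P = flag(report$calls$ponatinib)
    )
  }
  union_row <- tibble(
    sample = report$sample_id, row_type = "sample_union",
    variant = report$classification, vaf = NA_real_, depth = NA_real_,
    hotspot = NA,
    I = flag("imatinib" %in% report$tki_union),
    D = flag("dasatinib" %in% report$tki_union),
    N = flag("nilotinib" %in% report$tki_union),
    B = flag("bosutinib" %in% report$tki_union),
    P = flag("ponatinib" %in% report$tki_union)
  )
  bind_rows(variant_rows, union_row)
}

#' @rdname render_report
#' @param path Path to a `.report.json` written by [render_report()].
#' @export
read_sample_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls <- as_tibble(p$calls)
  if (nrow(calls) == 0) calls <- annotate_calls(empty_calls())
  # all-NA columns deserialize as logical; restore canonical types
  template <- annotate_calls(empty_calls())
  for (nm in intersect(names(template), names(calls))) {
    calls[[nm]] <- switch(class(template[[nm]])[1],
      integer = as.integer(calls[[nm]]),
      numeric = as.numeric(calls[[nm]]),
      character = as.character(calls[[nm]]),
      logical = as.logical(calls[[nm]]),
      calls[[nm]]
    )
  }
  calls <- new_kd_calls(calls)
  qc <- p$qc
  if (!is.null(qc)) {
    # JSON nulls (NA fields) come back as NULL list entries
    qc[vapply(qc, is.null, logical(1))] <- NA
    qc <- as_tibble(qc)
    if (!is.null(qc$reasons) && is.logical(qc$reasons)) {
      qc$reasons <- as.character(qc$reasons)
    }
    if (!is.null(qc$action) && is.logical(qc$action)) {
      qc$action <- as.character(qc$action)
    }
    qc <- structure(qc, class = c("kd_qc", class(qc)))
  }
  structure(
    list(sample_id = p$sample_id, qc = qc, calls = calls,
         classification = p$classification,
         tki_union = as.character(unlist(p$tki_union))),
    class = "kd_sample_report"
  )
}

#' Build truth-level sample reports from a cohort spec
#'
#' Converts each cohort-spec sample directly into a `kd_sample_report` using
#' the spike truth (protein change and target VAF) without simulating reads —
#' the deterministic route for spectrum summaries over a designed cohort.
#' Depth and alt counts are therefore reported as `NA`.
#'
#' @param spec A cohort spec tibble (see [default_cohort_spec()]).
#' @param catalogue A `kd_catalogue`.
#' @return Named list of `kd_sample_report`.
#' @export
reports_from_truth <- function(spec, catalogue = hotspot_catalogue()) {
  ids <- unique(spec$sample_id)
  reports <- lapply(ids, function(id) {
    rows <- filter(spec, .data$sample_id == id, !is.na(.data$protein_change))
    calls <- if (nrow(rows) == 0) empty_calls() else {
      p <- parse_hotspot_notation(rows$protein_change)
      tibble(
        kd_pos = NA_integer_, ref_base = NA_character_, alt_base = NA_character_,
        codon = p$codon, protein_change = p$protein_change, synonymous = FALSE,
        vaf = rows$target_vaf, depth = NA_real_, alt_count = NA_integer_,
        passes_lod = TRUE, in_catalogue = p$protein_change %in% catalogue$protein_change,
        multi_hit = nrow(rows) > 1L
      )
    }
    classify_sample(new_kd_calls(calls), catalogue, sample_id = id)
  })
  setNames(reports, ids)
}

#' Tidy methods for sample reports
#'
#' `tidy()` returns the annotated call table with the sample id prepended;
#' `glance()` returns a one-row summary.
#'
#' @param x A `kd_sample_report`.
#' @param ... Unused.
#' @method tidy kd_sample_report
#' @export
tidy.kd_sample_report <- function(x, ...) {
  mutate(as_tibble(x$calls), sample_id = x$sample_id, .before = 1)
}

#' @rdname tidy.kd_sample_report
#' @method glance kd_sample_report
#' @export
glance.kd_sample_report <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    classification = x$classification,
    n_variants = nrow(x$calls),
    max_vaf = if (nrow(x$calls)) max(x$calls$vaf) else NA_real_,
    tki_union = paste(x$tki_union, collapse = ";"),
    qc_pass = if (is.null(x$qc)) NA else x$qc$pass[1]
  )
}
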