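# Transparent pileup variant caller: read-to-amplicon assignment, base counts
# over the KD window, sample QC gates, and LOD-thresholded substitution calls.

#' Assign reads to amplicons by their 5' anchor
#'
#' Each read's 5' prefix is compared against every amplicon's terminal 20-mer
#' in both orientations; a read is assigned to the amplicon it matches with at
#' most `max_primer_mismatches` mismatches (exact matches are resolved first,
#' the remainder by a mismatch scan; ties go to the fewest-mismatch anchor).
#' Reverse-orientation reads are re-oriented to the forward strand.
#' Unassignable reads are counted as off-target, not errors.
#'
#' @param reads Tibble with `read_id` and `seq` (as from [simulate_sample()]
#'   or [read_fastq()]).
#' @param panel A `kd_panel`.
#' @param max_primer_mismatches Maximum anchor mismatches (default 2).
#' @return A `kd_assignment` tibble: `read_id`, `amplicon_id` (`NA` for
#'   off-target), `orientation`, `seq` (re-oriented).
#' @export
assign_reads <- function(reads, panel, max_primer_mismatches = 2) {
  k <- PANEL_PRIMER_LEN
  anchors <- panel_anchors(panel, k)
  prefix <- substr(reads$seq, 1L, k)
  hit <- match(prefix, anchors$anchor)

  todo <- which(is.na(hit) & nchar(reads$seq) >= k)
  if (length(todo) > 0 && max_primer_mismatches > 0) {
    pref_mat <- matrix(unlist(strsplit(prefix[todo], "", fixed = TRUE), use.names = FALSE),
                       nrow = length(todo), byrow = TRUE)
    best_mm <- rep.int(k + 1L, length(todo))
    best_anchor <- rep(NA_integer_, length(todo))
    for (a in seq_len(nrow(anchors))) {
      ach <- strsplit(anchors$anchor[a], "", fixed = TRUE)[[1]]
      mm <- rowSums(pref_mat != matrix(ach, nrow = length(todo), ncol = k, byrow = TRUE))
      better <- mm < best_mm
      best_mm[better] <- mm[better]
      best_anchor[better] <- a
    }
    ok <- best_mm <= max_primer_mismatches
    hit[todo[ok]] <- best_anchor[ok]
  }

  amplicon_id <- anchors$amplicon_id[hit]
  orientation <- anchors$orientation[hit]
  seq_out <- reads$seq
  is_rev <- !is.na(orientation) & orientation == "rev"
  if (any(is_rev)) seq_out[is_rev] <- revcomp(seq_out[is_rev])
  out <- tibble(
    read_id = reads$read_id,
    amplicon_id = amplicon_id,
    orientation = orientation,
    seq = seq_out
  )
  structure(out, class = c("kd_assignment", class(out)))
}

#' Build the base-level pileup over the KD window
#'
#' Every assigned read contributes one count per covered non-primer position
#' of its amplicon; positions inside an amplicon's primer regions are
#' excluded, and positions covered by overlapping amplicons accumulate counts
#' from all of them. Reads whose length does not match their amplicon are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param assignment A `kd_assignment` from [assign_reads()].
#' @param panel A `kd_panel`.
#' @return A `kd_pileup` tibble: `kd_pos` (0-based), `ref_base`, `A`, `C`,
#'   `G`, `T`, `depth`; attribute `n_skipped`.
#' @export
build_pileup <- function(assignment, panel) {
  ref <- attr(panel, "reference")
  L <- nchar(ref$kd_sequence)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  n_skipped <- 0L
  for (i in seq_len(nrow(panel))) {
    rows <- !is.na(assignment$amplicon_id) & assignment$amplicon_id == panel$amplicon_id[i]
    if (!any(rows)) next
    seqs <- assignment$seq[rows]
    len <- panel$end[i] - panel$start[i]
    bad <- nchar(seqs) != len
    n_skipped <- n_skipped + sum(bad)
    seqs <- seqs[!bad]
    if (length(seqs) == 0) next
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    amp_counts <- matrix(0L, nrow = 4L, ncol = len)
    present <- intersect(rownames(cm), c("A", "C", "G", "T"))
    amp_counts[match(present, c("A", "C", "G", "T")), ] <- cm[present, , drop = FALSE]
    keep <- seq_len(len) > panel$fwd_primer_len[i] &
      seq_len(len) <= len - panel$rev_primer_len[i]
    amp_counts[, !keep] <- 0L
    cols <- seq.int(panel$start[i] + 1L, panel$end[i])
    counts[, cols] <- counts[, cols] + amp_counts
  }
  out <- tibble(
    kd_pos = seq_len(L) - 1L,
    ref_base = strsplit(ref$kd_sequence, "", fixed = TRUE)[[1]],
    A = counts["A", ], C = counts["C", ], G = counts["G", ], T = counts["T", ],
    depth = colSums(counts)
  )
  structure(out, class = c("kd_pileup", class(out)),
            n_skipped = n_skipped, reference = ref)
}

#' QC gate thresholds
#'
#' @param min_total_reads Minimum reads per library (assay gate: 100,000;
#'   failing libraries are tagged for repeat sequencing). The fast simulation
#'   profile uses 10,000 so the gate logic is exercised at desk scale.
#' @param min_on_target Minimum assignable-read fraction (strict `>`; assay
#'   gate 0.99).
#' @param profile Optional `"full"`/`"fast"` shortcut for `min_total_reads`.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(min_total_reads = 100000, min_on_target = 0.99,
                          profile = NULL) {
  if (!is.null(profile)) {
    profile <- arg_match(profile, c("fast", "full"))
    min_total_reads <- if (profile == "full") 100000 else 10000
  }
  list(min_total_reads = as.integer(min_total_reads), min_on_target = min_on_target)
}

#' Per-sample sequencing QC
#'
#' A sample passes when `total_reads >= min_total_reads` and
#' `on_target_fraction > min_on_target`. Each failed gate is named in
#' `reasons`; a read-count failure additionally carries the action tag
#' `repeat_sequencing`.
#'
#' @param assignment A `kd_assignment`.
#' @param pileup A `kd_pileup` (for the mean-depth report field).
#' @param thresholds A [qc_thresholds()] list.
#' @param sample_id Sample identifier.
#' @return One-row `kd_qc` tibble: `sample_id`, `total_reads`,
#'   `assigned_reads`, `on_target_fraction`, `mean_depth`, `pass`, `reasons`
#'   (semicolon-joined, `""` when passing), `action`.
#' @export
qc_sample <- function(assignment, pileup, thresholds = qc_thresholds(),
                      sample_id = "sample") {
  total <- nrow(assignment)
  assigned <- sum(!is.na(assignment$amplicon_id))
  frac <- if (total > 0) assigned / total else 0
  reasons <- character(0)
  action <- NA_character_
  if (total < thresholds$min_total_reads) {
    reasons <- c(reasons, sprintf("total_reads %d < %d", total, thresholds$min_total_reads))
    action <- "repeat_sequencing"
  }
  if (frac <= thresholds$min_on_target) {
    reasons <- c(reasons, sprintf("on_target_fraction %.4f <= %.2f",
                                  frac, thresholds$min_on_target))
  }
  out <- tibble(
    sample_id = sample_id,
    total_reads = total,
    assigned_reads = assigned,
    on_target_fraction = frac,
    mean_depth = mean(pileup$depth),
    pass = length(reasons) == 0,
    reasons = paste(reasons, collapse = "; "),
    action = action
  )
  structure(out, class = c("kd_qc", class(out)))
}

#' Variant-calling parameters
#'
#' @param lod_percent Limit of detection in percent VAF (inclusive: a call at
#'   exactly 2.00% passes, matching the assay's declared 2% LOD).
#' @param min_alt_reads Minimum alternate-read count (guard against calls
#'   supported by a handful of reads at low depth).
#' @param min_depth Minimum depth at the position.
#' @return Named list of parameters.
#' @export
call_params <- function(lod_percent = 2.0, min_alt_reads = 10L, min_depth = 500L) {
  list(lod_percent = lod_percent, min_alt_reads = as.integer(min_alt_reads),
       min_depth = as.integer(min_depth))
}

#' Call substitution variants from a pileup
#'
#' For every position and every non-reference base observed there, computes
#' `VAF = 100 * alt_count / depth`, maps the call to its codon, names the
#' protein change under the standard genetic code, and flags catalogue
#' membership. A call passes the LOD when `vaf >= lod_percent`,
#' `alt_count >= min_alt_reads` and `depth >= min_depth`. Two passing calls in
#' one codon are emitted separately with a multi-hit warning (phasing is not
#' attempted).
#'
#' @param pileup A `kd_pileup`.
#' @param catalogue A `kd_catalogue` for hotspot lookup.
#' @param params A [call_params()] list.
#' @param all If `TRUE`, return every non-reference observation with its
#'   `passes_lod` flag; by default only passing calls are returned.
#' @return A `kd_calls` tibble sorted by position then descending VAF:
#'   `kd_pos`, `ref_base`, `alt_base`, `codon`, `protein_change`,
#'   `synonymous`, `vaf`, `depth`, `alt_count`, `passes_lod`, `in_catalogue`,
#'   `multi_hit`.
#' @export
call_variants <- function(pileup, catalogue = hotspot_catalogue(),
                          params = call_params(), all = FALSE) {
  if (sum(pileup$depth) == 0) {
    abort_abl1kd("no coverage: the pileup is empty", "abl1kd_no_coverage_error")
  }
  ref <- attr(pileup, "reference")
  long <- pileup |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"),
                        names_to = "alt_base", values_to = "alt_count") |>
    filter(.data$alt_base != .data$ref_base, .data$alt_count > 0L)
  if (!all) {
    # cheap pre-filter: nothing below these can pass
    long <- filter(long,
      .data$alt_count >= params$min_alt_reads,
      .data$depth >= params$min_depth,
      100 * .data$alt_count / .data$depth >= params$lod_percent)
  }
  if (nrow(long) == 0) {
    return(new_kd_calls(empty_calls()))
  }
  named <- name_protein_change(long$kd_pos, long$alt_base, ref)
  calls <- long |>
    mutate(
      vaf = 100 * .data$alt_count / .data$depth,
      codon = named$codon,
      protein_change = named$protein_change,
      synonymous = named$synonymous,
      passes_lod = .data$vaf >= params$lod_percent &
        .data$alt_count >= params$min_alt_reads &
        .data$depth >= params$min_depth,
      in_catalogue = .data$protein_change %in% catalogue$protein_change
    ) |>
    arrange(.data$kd_pos, desc(.data$vaf)) |>
    select("kd_pos", "ref_base", "alt_base", "codon", "protein_change",
           "synonymous", "vaf", "depth", "alt_count", "passes_lod", "in_catalogue")
  if (!all) calls <- filter(calls, .data$passes_lod)
  calls <- calls |>
    group_by(.data$codon) |>
    mutate(multi_hit = sum(.data$passes_lod) > 1L) |>
    ungroup()
  if (any(calls$multi_hit & calls$passes_lod)) {
    warn(paste0("multiple passing substitutions in codon(s): ",
                paste(unique(calls$codon[calls$multi_hit & calls$passes_lod]),
                      collapse = ", ")))
  }
  new_kd_calls(calls)
}

empty_calls <- function() {
  tibble(
    kd_pos = integer(), ref_base = character(), alt_base = character(),
    codon = integer(), protein_change = character(), synonymous = logical(),
    vaf = numeric(), depth = numeric(), alt_count = integer(),
    passes_lod = logical(), in_catalogue = logical(), multi_hit = logical()
  )
}

new_kd_calls <- function(tbl) {
  structure(tbl, class = unique(c("kd_calls", class(tbl))))
}

#' Name the protein change of a substitution
#'
#' Mutates the containing codon at the in-codon offset, translates both codons
#' under the standard genetic code and formats `<wt><codon><mut>`. Synonymous
#' changes render with `wt == mut` and are flagged.
#'
#' @param kd_pos 0-based KD-local position(s).
#' @param alt_base Alternate base(s).
#' @param ref A `kd_reference`.
#' @return Tibble with `codon`, `wt`, `mut`, `protein_change`, `synonymous`.
#' @examples
#' ref <- build_surrogate_reference(seed = 1)
#' rng <- codon_to_base_range(315, ref)
#' name_protein_change(rng$start + 1L, "T", ref)
#' @export
name_protein_change <- function(kd_pos, alt_base, ref) {
  kd_pos <- as.integer(kd_pos)
  if (any(kd_pos < 0L | kd_pos >= nchar(ref$kd_sequence))) {
    abort_abl1kd("position outside the KD window", "abl1kd_range_error")
  }
  codon_idx <- kd_pos %/% 3L
  codon_start <- 3L * codon_idx + 1L
  wt_codon <- substring(ref$kd_sequence, codon_start, codon_start + 2L)
  offset <- kd_pos - 3L * codon_idx + 1L
  mut_codon <- wt_codon
  substr(mut_codon, offset, offset) <- alt_base
  wt <- translate_codons(wt_codon)
  mut <- translate_codons(mut_codon)
  codon <- ref$first_codon + codon_idx
  tibble(
    codon = codon, wt = wt, mut = mut,
    protein_change = paste0(wt, codon, mut),
    synonymous = wt == mut
  )
}

#' Run assignment, pileup, QC and calling in one step
#'
#' @param reads Reads tibble.
#' @param panel A `kd_panel`.
#' @param catalogue A `kd_catalogue`.
#' @param params A [call_params()].
#' @param thresholds A [qc_thresholds()].
#' @param sample_id Sample identifier.
#' @return List with `assignment`, `pileup`, `qc`, `calls`.
#' @export
call_sample <- function(reads, panel, catalogue = hotspot_catalogue(),
                        params = call_params(), thresholds = qc_thresholds(),
                        sample_id = "sample") {
  assignment <- assign_reads(reads, panel)
  pileup <- build_pileup(assignment, panel)
  qc <- qc_sample(assignment, pileup, thresholds, sample_id = sample_id)
  calls <- call_variants(pileup, catalogue, params)
  list(assignment = assignment, pileup = pileup, qc = qc, calls = calls)
}
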