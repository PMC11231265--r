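# Amplicon panel: 12 overlapping 200-250 bp amplicons tiling the KD window,
# split across two primer pools so adjacent amplicons never share a reaction.

PANEL_N_AMPLICONS <- 12L
PANEL_MIN_LEN <- 200L
PANEL_MAX_LEN <- 250L
PANEL_PRIMER_LEN <- 20L
PANEL_MIN_OVERLAP <- 20L  # non-primer overlap between adjacent amplicons

#' Build the 12-amplicon tiling panel
#'
#' Places 12 amplicons of 200-250 bp over the 1023-base KD window with even,
#' seed-jittered spacing. Each amplicon carries 20-base primer regions at both
#' ends (excluded from variant calling), except that the first amplicon has no
#' forward primer inside the window and the last no reverse primer (terminal
#' primers sit in flanking fusion-transcript sequence), so every KD base lies
#' in at least one amplicon's non-primer interior. Adjacent amplicons overlap
#' by at least 20 non-primer bases and alternate between pools 1 and 2.
#'
#' @param ref A `kd_reference`.
#' @param seed Integer seed controlling the jitter; the same seed always
#'   yields the same panel.
#' @return A `kd_panel`: tibble with columns `amplicon_id`, `start`, `end`
#'   (0-based, half-open, KD-local), `pool`, `fwd_primer_len`,
#'   `rev_primer_len`, `seq` (full amplicon sequence), with the reference
#'   stored in attribute `reference`.
#' @examples
#' ref <- build_surrogate_reference(seed = 1)
#' panel <- build_amplicon_panel(ref, seed = 1)
#' panel[, c("amplicon_id", "start", "end", "pool")]
#' @export
build_amplicon_panel <- function(ref, seed = 1) {
  L <- nchar(ref$kd_sequence)
  n <- PANEL_N_AMPLICONS
  for (attempt in 0:9) {
    geom <- withr::with_seed(derive_seed(seed, attempt), {
      len <- sample(215:240, n, replace = TRUE)
      start <- round((L - len[n]) * (seq_len(n) - 1L) / (n - 1L)) +
        c(0L, sample(-10:10, n - 2L, replace = TRUE), 0L)
      start[1] <- 0L
      start[n] <- L - len[n]
      list(start = as.integer(start), len = as.integer(len))
    })
    tbl <- tibble(
      amplicon_id = sprintf("AMP%02d", seq_len(n)),
      start = geom$start,
      end = geom$start + geom$len,
      pool = rep_len(c(1L, 2L), n),
      fwd_primer_len = c(0L, rep(PANEL_PRIMER_LEN, n - 1L)),
      rev_primer_len = c(rep(PANEL_PRIMER_LEN, n - 1L), 0L)
    )
    panel <- try(new_kd_panel(tbl, ref), silent = TRUE)
    if (!inherits(panel, "try-error")) return(panel)
  }
  abort_abl1kd("could not construct a valid amplicon panel", "abl1kd_construction_error")
}

new_kd_panel <- function(tbl, ref) {
  tbl <- mutate(tbl,
    seq = substring(ref$kd_sequence, .data$start + 1L, .data$end)
  )
  panel <- structure(tbl, class = c("kd_panel", class(tbl)), reference = ref)
  validate_panel(panel)
  panel
}

#' Validate a panel against its design invariants
#'
#' Checks amplicon count, length bounds, window containment, gap-free
#' non-primer coverage of every KD base, minimum non-primer overlap between
#' adjacent amplicons, and pool alternation. Called automatically by panel
#' constructors; exported so user-supplied BED panels can be checked too.
#'
#' @param panel A `kd_panel`.
#' @return `panel`, invisibly; errors with class `abl1kd_construction_error`
#'   on any violation.
#' @export
validate_panel <- function(panel) {
  ref <- attr(panel, "reference")
  L <- nchar(ref$kd_sequence)
  fail <- function(msg) abort_abl1kd(msg, "abl1kd_construction_error")
  if (nrow(panel) != PANEL_N_AMPLICONS) fail("panel must have exactly 12 amplicons")
  len <- panel$end - panel$start
  if (any(len < PANEL_MIN_LEN | len > PANEL_MAX_LEN)) {
    fail("amplicon lengths must be within 200-250 bp")
  }
  if (any(panel$start < 0L) || any(panel$end > L)) fail("amplicon outside the KD window")
  if (is.unsorted(panel$start, strictly = TRUE)) fail("amplicons must be ordered by start")
  if (any(panel$pool[-1] == panel$pool[-nrow(panel)])) {
    fail("adjacent amplicons must be in different pools")
  }
  int_start <- panel$start + panel$fwd_primer_len
  int_end <- panel$end - panel$rev_primer_len
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(panel))) {
    covered[seq.int(int_start[i] + 1L, int_end[i])] <- TRUE
  }
  if (!all(covered)) fail("non-primer interiors leave uncovered KD bases")
  overlap <- int_end[-nrow(panel)] - int_start[-1]
  if (any(overlap < PANEL_MIN_OVERLAP)) {
    fail("adjacent amplicons must overlap by >= 20 non-primer bases")
  }
  invisible(panel)
}

#' @export
print.kd_panel <- function(x, ...) {
  cat("KD amplicon panel: ", nrow(x), " amplicons over ",
      nchar(attr(x, "reference")$kd_sequence), " bases\n", sep = "")
  NextMethod()
}

# Terminal 20-mer anchors used for read-to-amplicon assignment: the forward
# anchor is the amplicon's first 20 bases; the reverse anchor is the first 20
# bases of the reverse-complemented amplicon.
panel_anchors <- function(panel, k = PANEL_PRIMER_LEN) {
  fwd <- substr(panel$seq, 1L, k)
  rev <- substr(revcomp(panel$seq), 1L, k)
  tibble(
    amplicon_id = rep(panel$amplicon_id, 2L),
    orientation = rep(c("fwd", "rev"), each = nrow(panel)),
    anchor = c(fwd, rev)
  )
}

#' Export / import a panel as BED (+ primer-length TSV)
#'
#' The BED file is 0-based half-open with `name` = amplicon id and the score
#' column carrying the pool number. Primer lengths travel in a sibling TSV
#' (`<path>.primers.tsv`) because BED has no field for them.
#'
#' @param panel A `kd_panel`.
#' @param path BED output path.
#' @return `write_panel_bed()` returns `path` invisibly; `read_panel_bed()`
#'   returns a `kd_panel`.
#' @param ref A `kd_reference` for sequence reconstruction and validation.
#' @export
write_panel_bed <- function(panel, path) {
  ref <- attr(panel, "reference")
  gr <- GenomicRanges::GRanges(
    seqnames = ref$label,
    ranges = IRanges::IRanges(start = panel$start + 1L, end = panel$end),
    name = panel$amplicon_id,
    score = panel$pool
  )
  GenomeInfoDb::seqlengths(gr) <- nchar(ref$kd_sequence)
  rtracklayer::export(gr, path, format = "BED")
  readr::write_tsv(
    as_tibble(panel)[, c("amplicon_id", "fwd_primer_len", "rev_primer_len")],
    paste0(path, ".primers.tsv")
  )
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path, ref) {
  gr <- rtracklayer::import(path, format = "BED")
  primers <- readr::read_tsv(paste0(path, ".primers.tsv"), col_types = "cii")
  tbl <- tibble(
    amplicon_id = gr$name,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    pool = as.integer(gr$score)
  ) |>
    left_join(primers, by = "amplicon_id") |>
    arrange(.data$start)
  new_kd_panel(tbl, ref)
}
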