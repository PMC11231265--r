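# Shared numeric and seeding helpers.

#' Render a percentage under one of the assay's reporting conventions
#'
#' Validation statistics are stored at full precision and only rounded when
#' rendered. Three conventions are supported because published assay reports
#' mix them: `"half_up_2dp"` (round half away from zero to 2 decimals, e.g.
#' 92.857 -> 92.86), `"truncate_2dp"` (drop digits past the second decimal,
#' e.g. 95.238 -> 95.23) and `"integer"` (round half up to a whole percent,
#' e.g. 87.5 -> 88).
#'
#' @param x Numeric vector of percentages (or any numeric to round).
#' @param mode One of `"half_up_2dp"`, `"truncate_2dp"`, `"integer"`.
#' @return Numeric vector, rounded per `mode`. `NA` passes through.
#' @examples
#' render_percent(92.8571, "half_up_2dp")
#' render_percent(100 * 20 / 21, "truncate_2dp")
#' render_percent(87.5, "integer")
#' @export
render_percent <- function(x, mode = c("half_up_2dp", "truncate_2dp", "integer")) {
  mode <- arg_match(mode)
  # small epsilon guards against 591.4999... style binary representation of
  # values that are exactly representable in decimal
  eps <- 1e-9
  switch(mode,
    half_up_2dp  = sign(x) * floor(abs(x) * 100 + 0.5 + eps) / 100,
    truncate_2dp = sign(x) * floor(abs(x) * 100 + eps) / 100,
    integer      = sign(x) * floor(abs(x) + 0.5 + eps)
  )
}

# Deterministic child seed for replicate/cohort/sample k under a parent seed.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483629 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Reverse complement for plain character vectors (ACGT alphabet).
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised random DNA of given lengths.
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

abort_abl1kd <- function(msg, class) {
  abort(msg, class = c(class, "abl1kd_error"))
}
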