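# Independent brute-force oracles. Deliberately naive: character-by-character
# loops and closed-form algebra, sharing no code with the package internals.

oracle_revcomp1 <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Re-implements assign + pileup + threshold calling with plain loops.
# panel_df: plain data.frame of the panel columns; ref_seq: character scalar.
oracle_call <- function(read_seqs, panel_df, ref_seq,
                        lod = 2, min_alt = 10, min_depth = 500, max_mm = 2) {
  n_amp <- nrow(panel_df)
  anchors <- character(2 * n_amp)
  for (i in seq_len(n_amp)) {
    anchors[i] <- substr(panel_df$seq[i], 1, 20)
    rc <- oracle_revcomp1(panel_df$seq[i])
    anchors[n_amp + i] <- substr(rc, 1, 20)
  }
  L <- nchar(ref_seq)
  counts <- matrix(0, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in read_seqs) {
    if (nchar(s) < 20) next
    pref <- strsplit(substr(s, 1, 20), "")[[1]]
    best_mm <- max_mm + 1
    best_a <- NA
    for (a in seq_along(anchors)) {
      anc <- strsplit(anchors[a], "")[[1]]
      mm <- 0
      for (j in 1:20) if (pref[j] != anc[j]) mm <- mm + 1
      if (mm < best_mm) { best_mm <- mm; best_a <- a }
    }
    if (is.na(best_a)) next
    amp <- if (best_a > n_amp) best_a - n_amp else best_a
    oriented <- if (best_a > n_amp) oracle_revcomp1(s) else s
    if (nchar(oriented) != panel_df$end[amp] - panel_df$start[amp]) next
    chars <- strsplit(oriented, "")[[1]]
    for (j in seq_along(chars)) {
      if (j <= panel_df$fwd_primer_len[amp]) next
      if (j > length(chars) - panel_df$rev_primer_len[amp]) next
      pos <- panel_df$start[amp] + j  # 1-based column
      counts[chars[j], pos] <- counts[chars[j], pos] + 1
    }
  }
  out <- NULL
  ref_chars <- strsplit(ref_seq, "")[[1]]
  for (pos in seq_len(L)) {
    depth <- sum(counts[, pos])
    for (b in c("A", "C", "G", "T")) {
      if (b == ref_chars[pos]) next
      alt <- counts[b, pos]
      if (alt == 0) next
      vaf <- 100 * alt / depth
      if (vaf >= lod && alt >= min_alt && depth >= min_depth) {
        out <- rbind(out, data.frame(kd_pos = pos - 1L, alt_base = b,
                                     vaf = vaf, depth = depth, alt_count = alt))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(kd_pos = integer(), alt_base = character(),
                      vaf = numeric(), depth = numeric(), alt_count = numeric()))
  }
  out <- out[order(out$kd_pos, -out$vaf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Closed-form normal-equation OLS (y ~ x), plus R^2.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
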