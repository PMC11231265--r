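test_that("reads are assigned to their amplicon in either orientation", {
  reads <- tibble::tibble(
    read_id = c("f", "r"),
    seq = c(PANEL$seq[3], abl1kd:::revcomp(PANEL$seq[3]))
  )
  asg <- assign_reads(reads, PANEL)
  expect_equal(asg$amplicon_id, c("AMP03", "AMP03"))
  expect_equal(asg$orientation, c("fwd", "rev"))
  # re-oriented sequences are identical
  expect_identical(asg$seq[1], asg$seq[2])

  # up to 2 anchor mismatches are tolerated; 3 are not
  mm2 <- PANEL$seq[3]
  substr(mm2, 2, 2) <- setdiff(c("A","C","G","T"), substr(mm2, 2, 2))[1]
  substr(mm2, 9, 9) <- setdiff(c("A","C","G","T"), substr(mm2, 9, 9))[1]
  mm3 <- mm2
  substr(mm3, 15, 15) <- setdiff(c("A","C","G","T"), substr(mm3, 15, 15))[1]
  asg2 <- assign_reads(tibble::tibble(read_id = c("m2", "m3"), seq = c(mm2, mm3)), PANEL)
  expect_equal(asg2$amplicon_id, c("AMP03", NA))
})

test_that("uniform random reads are effectively never assigned", {
  reads <- withr::with_seed(99, tibble::tibble(
    read_id = sprintf("r%05d", 1:10000),
    seq = abl1kd:::random_dna(rep(220L, 10000))
  ))
  asg <- assign_reads(reads, PANEL)
  # chance of <=2 mismatches over a 20-mer anchor is ~1e-7 per comparison
  expect_lt(sum(!is.na(asg$amplicon_id)), 5)
})

test_that("pileup has per-amplicon depth, additive overlaps, primer exclusion", {
  amp <- PANEL[4, ]
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    seq = rep(amp$seq, 100)
  )
  pu <- build_pileup(assign_reads(reads, PANEL), PANEL)
  interior <- seq.int(amp$start + amp$fwd_primer_len, amp$end - amp$rev_primer_len - 1L)
  expect_true(all(pu$depth[pu$kd_pos %in% interior] == 100))
  outside <- setdiff(pu$kd_pos, seq.int(amp$start, amp$end - 1L))
  expect_true(all(pu$depth[pu$kd_pos %in% outside] == 0))
  # primer positions of this amplicon contribute nothing
  primer_pos <- c(seq.int(amp$start, amp$start + amp$fwd_primer_len - 1L),
                  seq.int(amp$end - amp$rev_primer_len, amp$end - 1L))
  expect_true(all(pu$depth[pu$kd_pos %in% primer_pos] == 0))

  # overlap additivity: 100 reads each on two adjacent amplicons
  reads2 <- tibble::tibble(
    read_id = sprintf("s%03d", 1:200),
    seq = c(rep(PANEL$seq[4], 100), rep(PANEL$seq[5], 100))
  )
  pu2 <- build_pileup(assign_reads(reads2, PANEL), PANEL)
  ov <- seq.int(PANEL$start[5] + PANEL$fwd_primer_len[5],
                PANEL$end[4] - PANEL$rev_primer_len[4] - 1L)
  expect_true(length(ov) >= 20)
  expect_true(all(pu2$depth[pu2$kd_pos %in% ov] == 200))
})

test_that("pileup counts alt and ref reads exactly", {
  amp <- PANEL[2, ]
  pos <- amp$start + 50L  # interior position
  alt_seq <- amp$seq
  off <- pos - amp$start + 1L
  ref_b <- substr(alt_seq, off, off)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  substr(alt_seq, off, off) <- alt_b
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:200),
    seq = c(rep(alt_seq, 50), rep(amp$seq, 150))
  )
  pu <- build_pileup(assign_reads(reads, PANEL), PANEL)
  row <- dplyr::filter(pu, kd_pos == pos)
  expect_equal(row[[alt_b]], 50L)
  expect_equal(row[[ref_b]], 150L)
  expect_equal(row$depth, 200)
})

test_that("QC gates follow the read-count and on-target thresholds", {
  mk_asg <- function(total, assigned) {
    tibble::tibble(
      read_id = sprintf("r%d", seq_len(total)),
      amplicon_id = c(rep("AMP01", assigned), rep(NA, total - assigned)),
      orientation = NA_character_, seq = NA_character_
    )
  }
  pu0 <- structure(tibble::tibble(depth = rep(1000, 10)), reference = REF)
  qc1 <- qc_sample(mk_asg(500000, 497500), pu0, qc_thresholds())
  expect_true(qc1$pass)
  expect_equal(qc1$reasons, "")
  qc2 <- qc_sample(mk_asg(90000, 89900), pu0, qc_thresholds())
  expect_false(qc2$pass)
  expect_match(qc2$reasons, "total_reads")
  expect_equal(qc2$action, "repeat_sequencing")
  qc3 <- qc_sample(mk_asg(200000, 190000), pu0, qc_thresholds())
  expect_false(qc3$pass)
  expect_match(qc3$reasons, "on_target")
  expect_false(grepl("total_reads", qc3$reasons))
  expect_true(is.na(qc3$action))
  # boundary: exactly 99% on-target fails the strict > gate
  qc4 <- qc_sample(mk_asg(100000, 99000), pu0, qc_thresholds())
  expect_false(qc4$pass)
})

test_that("LOD boundary is inclusive at 2.00% and filters 1.95%", {
  # hand-built pileup rows via reads: 2000 reads, 40 vs 39 alt
  amp <- PANEL[6, ]
  pos <- abl1kd:::resolve_spikes(spike_spec("T315I", 50), REF)$kd_pos
  stopifnot(pos >= amp$start, pos < amp$end)
  off <- pos - amp$start + 1L
  alt_seq <- amp$seq
  substr(alt_seq, off, off) <- abl1kd:::resolve_spikes(spike_spec("T315I", 50), REF)$alt_base
  mk <- function(n_alt) {
    tibble::tibble(
      read_id = sprintf("r%04d", 1:2000),
      seq = c(rep(alt_seq, n_alt), rep(amp$seq, 2000 - n_alt))
    )
  }
  calls40 <- call_variants(build_pileup(assign_reads(mk(40), PANEL), PANEL), CAT)
  expect_equal(nrow(calls40), 1L)
  expect_equal(calls40$vaf, 2.00)
  expect_equal(calls40$protein_change, "T315I")
  expect_true(calls40$passes_lod)

  calls39 <- call_variants(build_pileup(assign_reads(mk(39), PANEL), PANEL), CAT)
  expect_equal(nrow(calls39), 0L)
  all39 <- call_variants(build_pileup(assign_reads(mk(39), PANEL), PANEL), CAT, all = TRUE)
  row <- dplyr::filter(all39, kd_pos == pos, alt_base != ref_base)
  expect_equal(row$vaf, 1.95)
  expect_false(row$passes_lod)
})

test_that("a seeded F317L spike at 11.83% is recovered as one passing hotspot call", {
  pos <- spike_pos("F317L")
  cfg <- sim_config(reads_total = reads_for_depth(PANEL, pos, 2000), seed = 14)
  sim <- simulate_sample(PANEL, spike_spec("F317L", 11.83), cfg)
  res <- call_sample(sim$reads, PANEL, CAT, thresholds = QC_TINY)
  hot <- dplyr::filter(res$calls, in_catalogue)
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$protein_change, "F317L")
  expect_true(vaf_within_4sd(hot$vaf, 11.83, hot$depth))
})

test_that("protein-change naming follows the standard genetic code", {
  rng315 <- codon_to_base_range(315, REF)
  codon315 <- substring(REF$kd_sequence, rng315$start + 1, rng315$end)
  expect_equal(codon315, "ACT")  # canonical Thr codon at 315
  named <- name_protein_change(rng315$start + 1L, "T", REF)  # ACT -> ATT
  expect_equal(named$protein_change, "T315I")
  expect_false(named$synonymous)

  # third-base synonymous change: ACT -> ACC stays Thr
  syn <- name_protein_change(rng315$start + 2L, "C", REF)
  expect_equal(syn$protein_change, "T315T")
  expect_true(syn$synonymous)

  # independent codon-table check for F359V (TTT -> GTT)
  rng359 <- codon_to_base_range(359, REF)
  codon359 <- substring(REF$kd_sequence, rng359$start + 1, rng359$end)
  expect_equal(codon359, "TTT")
  named359 <- name_protein_change(rng359$start, "G", REF)
  expect_equal(named359$protein_change, "F359V")
  expect_equal(unname(Biostrings::GENETIC_CODE[["GTT"]]), "V")
})

test_that("raising the LOD never increases the number of passing calls", {
  cfg <- sim_config(reads_total = 6000, read_error_rate = 0.01, seed = 15)
  sim <- simulate_sample(PANEL, spike_spec(c("T315I", "F317L"), c(3, 40)), cfg)
  pu <- build_pileup(assign_reads(sim$reads, PANEL), PANEL)
  lods <- c(0.5, 1, 2, 3, 5, 50)
  n_calls <- vapply(lods, function(l) {
    nrow(suppressWarnings(
      call_variants(pu, CAT, call_params(lod_percent = l, min_depth = 100))))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("caller matches the brute-force oracle exactly on small read sets", {
  panel_df <- as.data.frame(PANEL)
  params <- call_params(lod_percent = 2, min_alt_reads = 2, min_depth = 10)
  for (seed in 1:6) {
    reads <- withr::with_seed(seed, {
      n <- sample(20:50, 1)
      amp_idx <- sample(1:12, n, replace = TRUE)
      seqs <- PANEL$seq[amp_idx]
      # plant a few substitutions and flips, plus junk reads
      for (j in seq_len(n)) {
        if (runif(1) < 0.5) {
          p <- sample(nchar(seqs[j]), 1)
          substr(seqs[j], p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        if (runif(1) < 0.5) seqs[j] <- abl1kd:::revcomp(seqs[j])
      }
      c(seqs, abl1kd:::random_dna(rep(225L, 2)))
    })
    got <- suppressWarnings(call_variants(
      build_pileup(assign_reads(tibble::tibble(
        read_id = as.character(seq_along(reads)), seq = reads), PANEL), PANEL),
      CAT, params
    ))
    want <- oracle_call(reads, panel_df, REF$kd_sequence,
                        lod = 2, min_alt = 2, min_depth = 10)
    expect_equal(got$kd_pos, want$kd_pos)
    expect_equal(got$alt_base, want$alt_base)
    expect_equal(got$alt_count, as.integer(want$alt_count))
    expect_equal(got$depth, want$depth)
    expect_equal(got$vaf, want$vaf, tolerance = 1e-12)
  }
})

test_that("an empty pileup errors with 'no coverage'", {
  empty <- build_pileup(
    assign_reads(tibble::tibble(read_id = "x", seq = strrep("A", 225)), PANEL),
    PANEL
  )
  expect_error(call_variants(empty, CAT), regexp = "no coverage",
               class = "abl1kd_no_coverage_error")
})
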