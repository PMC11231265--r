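# Seeded amplicon-read simulator: spike-ins at known VAFs, serial dilutions,
# replicate libraries and multi-sample cohorts.

#' Simulation configuration
#'
#' @param reads_total Total reads per sample. The `"fast"` profile (24,000
#'   reads) gives ~2000x per-amplicon depth at desk scale; the `"full"`
#'   profile targets the assay's 0.5 million read minimum.
#' @param read_error_rate Per-base substitution probability (uniform over the
#'   three other bases).
#' @param reverse_fraction Fraction of reads emitted reverse-complemented.
#' @param off_target_fraction Fraction of reads that are uniform random
#'   sequence of amplicon-typical length (exercises the on-target QC gate).
#' @param seed Integer seed; every simulator output is deterministic under it.
#' @param quality_char Constant Phred+33 quality symbol written to FASTQ
#'   (default "?" = Q30).
#' @param profile Optional shortcut: `"fast"` or `"full"`; sets
#'   `reads_total` and the QC gate [qc_thresholds()] pair naturally used with
#'   it.
#' @return A `kd_sim_config` list.
#' @examples
#' sim_config(profile = "fast", seed = 7)
#' @export
sim_config <- function(reads_total = 24000, read_error_rate = 0.002,
                       reverse_fraction = 0.5, off_target_fraction = 0.005,
                       seed = 1, quality_char = "?", profile = NULL) {
  if (!is.null(profile)) {
    profile <- arg_match(profile, c("fast", "full"))
    reads_total <- if (profile == "full") 500000 else 24000
  }
  probs <- c(read_error_rate, reverse_fraction, off_target_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort_abl1kd("probabilities must lie in [0, 1]", "abl1kd_validation_error")
  }
  if (reads_total <= 0) {
    abort_abl1kd("reads_total must be positive", "abl1kd_validation_error")
  }
  structure(
    list(reads_total = as.integer(reads_total), read_error_rate = read_error_rate,
         reverse_fraction = reverse_fraction, off_target_fraction = off_target_fraction,
         seed = as.integer(seed), quality_char = quality_char,
         profile = profile %||% "custom"),
    class = "kd_sim_config"
  )
}

#' Specify variant spike-ins
#'
#' A spike is either a protein-change string (resolved against the reference
#' to a single-base substitution) or an explicit KD-local substitution.
#'
#' @param protein_change Character vector of protein changes (e.g. "F317L"),
#'   or `NULL` when using explicit positions.
#' @param target_vaf Percent VAF in (0, 100], recycled to the number of spikes.
#' @param kd_pos,ref_base,alt_base Explicit 0-based substitution (alternative
#'   to `protein_change`).
#' @return Tibble with one row per spike.
#' @examples
#' spike_spec("F317L", 11.83)
#' @export
spike_spec <- function(protein_change = NULL, target_vaf,
                       kd_pos = NULL, ref_base = NULL, alt_base = NULL) {
  if (any(target_vaf <= 0 | target_vaf > 100)) {
    abort_abl1kd("target_vaf must be in (0, 100]", "abl1kd_validation_error")
  }
  if (!is.null(protein_change)) {
    tibble(protein_change = protein_change,
           kd_pos = NA_integer_, ref_base = NA_character_, alt_base = NA_character_,
           target_vaf = as.numeric(target_vaf))
  } else {
    tibble(protein_change = NA_character_,
           kd_pos = as.integer(kd_pos), ref_base = ref_base, alt_base = alt_base,
           target_vaf = as.numeric(target_vaf))
  }
}

# Resolve spikes to concrete (kd_pos, ref_base, alt_base); protein changes are
# mapped through the reference codon, taking the first single-base
# substitution in (offset, base) order that yields the mutant residue.
resolve_spikes <- function(spikes, ref) {
  if (is.null(spikes) || nrow(spikes) == 0) {
    return(tibble(protein_change = character(), kd_pos = integer(),
                  ref_base = character(), alt_base = character(),
                  target_vaf = numeric()))
  }
  rows <- lapply(seq_len(nrow(spikes)), function(i) {
    row <- spikes[i, ]
    if (!is.na(row$protein_change)) {
      p <- parse_hotspot_notation(row$protein_change)
      rng <- codon_to_base_range(p$codon, ref)
      wt_codon <- substring(ref$kd_sequence, rng$start + 1L, rng$end)
      wt_res <- translate_codons(wt_codon)
      if (wt_res != p$wt) {
        abort_abl1kd(sprintf(
          "reference codon %d encodes %s, not the %s of '%s'",
          p$codon, wt_res, p$wt, row$protein_change
        ), "abl1kd_validation_error")
      }
      subs <- single_subs_to(wt_codon, p$mut)
      if (nrow(subs) == 0) {
        abort_abl1kd(sprintf(
          "'%s' is not reachable from reference codon %s by one substitution",
          row$protein_change, wt_codon
        ), "abl1kd_validation_error")
      }
      tibble(protein_change = p$protein_change,
             kd_pos = rng$start + subs$offset[1] - 1L,
             ref_base = subs$ref_base[1], alt_base = subs$alt_base[1],
             target_vaf = row$target_vaf)
    } else {
      pos <- row$kd_pos
      if (is.na(pos) || pos < 0L || pos >= nchar(ref$kd_sequence)) {
        abort_abl1kd("explicit spike position outside the KD window",
                     "abl1kd_validation_error")
      }
      have <- substr(ref$kd_sequence, pos + 1L, pos + 1L)
      if (have != row$ref_base) {
        abort_abl1kd(sprintf("reference base at %d is %s, not %s",
                             pos, have, row$ref_base), "abl1kd_validation_error")
      }
      mutate(row, protein_change = NA_character_)
    }
  })
  bind_rows(rows)
}

#' Simulate one amplicon sequencing library
#'
#' Emits `reads_total` reads spanning their full amplicon (allocation across
#' the 12 amplicons is uniform), with each read covering a spiked position
#' carrying the alternate allele independently with probability
#' `target_vaf/100` (binomial sampling), per-base substitution errors applied
#' independently at `read_error_rate` (uniform over the other three bases),
#' a configurable fraction of reads reverse-complemented, and a configurable
#' fraction of uniform-random off-target reads. Byte-identical output under
#' the same seed.
#'
#' @param panel A `kd_panel`.
#' @param spikes A [spike_spec()] tibble, or `NULL` for a negative sample.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier used in read names and the truth record.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth` (a
#'   `kd_truth` list: `sample_id`, resolved `spikes` with realized alt-read
#'   and covering-read counts, per-amplicon read counts, and the config).
#' @examples
#' ref <- build_surrogate_reference(seed = 1)
#' panel <- build_amplicon_panel(ref, seed = 1)
#' sim <- simulate_sample(panel, spike_spec("T315I", 30),
#'                        sim_config(reads_total = 1200, seed = 5))
#' sim$truth$spikes
#' @export
simulate_sample <- function(panel, spikes = NULL, config = sim_config(),
                            sample_id = "sample") {
  ref <- attr(panel, "reference")
  resolved <- resolve_spikes(spikes, ref)
  # every spike must fall inside at least one amplicon
  if (nrow(resolved) > 0) {
    covered <- vapply(resolved$kd_pos, function(p) {
      any(panel$start <= p & p < panel$end)
    }, logical(1))
    if (any(!covered)) {
      abort_abl1kd("spike position not covered by any amplicon",
                   "abl1kd_validation_error")
    }
  }
  withr::with_seed(config$seed, {
    n_off <- round(config$reads_total * config$off_target_fraction)
    n_on <- config$reads_total - n_off
    n_amp <- nrow(panel)
    alloc <- rep(n_on %/% n_amp, n_amp)
    if (n_on %% n_amp > 0) alloc[seq_len(n_on %% n_amp)] <- alloc[seq_len(n_on %% n_amp)] + 1L

    spike_rows <- vector("list", nrow(resolved))
    if (nrow(resolved) > 0) {
      for (k in seq_len(nrow(resolved))) {
        spike_rows[[k]] <- mutate(resolved[k, ], alt_reads = 0L, covering_reads = 0L)
      }
    }

    all_reads <- vector("list", n_amp + 1L)
    for (i in seq_len(n_amp)) {
      m <- alloc[i]
      amp_seq <- panel$seq[i]
      len <- nchar(amp_seq)
      reads <- rep(amp_seq, m)
      if (nrow(resolved) > 0) {
        for (k in seq_len(nrow(resolved))) {
          pos <- resolved$kd_pos[k]
          if (pos >= panel$start[i] && pos < panel$end[i]) {
            off <- pos - panel$start[i] + 1L
            take <- runif(m) < resolved$target_vaf[k] / 100
            if (any(take)) substr(reads[take], off, off) <- resolved$alt_base[k]
            spike_rows[[k]]$alt_reads <- spike_rows[[k]]$alt_reads + sum(take)
            spike_rows[[k]]$covering_reads <- spike_rows[[k]]$covering_reads + m
          }
        }
      }
      reads <- apply_read_errors(reads, len, config$read_error_rate)
      flip <- runif(m) < config$reverse_fraction
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
      all_reads[[i]] <- tibble(
        read_id = sprintf("%s:%s:%05d", sample_id, panel$amplicon_id[i], seq_len(m)),
        seq = reads
      )
    }
    if (n_off > 0) {
      lens <- sample(nchar(panel$seq), n_off, replace = TRUE)
      all_reads[[n_amp + 1L]] <- tibble(
        read_id = sprintf("%s:offtarget:%05d", sample_id, seq_len(n_off)),
        seq = random_dna(lens)
      )
    }
    truth <- structure(
      list(
        sample_id = sample_id,
        spikes = if (nrow(resolved) > 0) bind_rows(spike_rows) |>
          mutate(sample_id = sample_id, .before = 1) else
          mutate(resolved, alt_reads = integer(0), covering_reads = integer(0)),
        amplicon_reads = tibble(amplicon_id = panel$amplicon_id, n_reads = alloc),
        n_off_target = n_off,
        config = config
      ),
      class = "kd_truth"
    )
    list(reads = bind_rows(all_reads), truth = truth)
  })
}

# Sprinkle substitution errors over m same-length reads.
apply_read_errors <- function(reads, len, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  m <- length(reads)
  n_err <- rbinom(1L, m * len, rate)
  if (n_err == 0) return(reads)
  ridx <- sample.int(m, n_err, replace = TRUE)
  pos <- sample.int(len, n_err, replace = TRUE)
  new <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
  # same read may be hit more than once: apply in duplicate-free passes
  while (length(ridx) > 0) {
    first <- !duplicated(ridx)
    i <- ridx[first]; p <- pos[first]; b <- new[first]
    cur <- substr(reads[i], p, p)
    # uniform over the three other bases: redraw collisions with current base
    clash <- b == cur
    while (any(clash)) {
      b[clash] <- sample(c("A", "C", "G", "T"), sum(clash), replace = TRUE)
      clash <- b == substr(reads[i], p, p)
    }
    substr(reads[i], p, p) <- b
    ridx <- ridx[!first]; pos <- pos[!first]; new <- new[!first]
  }
  reads
}

#' Simulate a 1:1 serial dilution series
#'
#' Sample 0 is the undiluted library; sample k (k = 1..`n_dilutions`) carries
#' every spike at `target_vaf / 2^k`, emulating serial 1:1 dilution with a
#' known-negative sample.
#'
#' @inheritParams simulate_sample
#' @param base_spikes [spike_spec()] of the undiluted sample.
#' @param n_dilutions Number of 1:1 dilution steps (>= 1).
#' @return List of `simulate_sample()` results, names `"D0"`..`"Dn"`.
#' @export
simulate_dilution_series <- function(panel, base_spikes, n_dilutions = 3,
                                     config = sim_config(), sample_id = "dilution") {
  if (n_dilutions < 1) {
    abort_abl1kd("n_dilutions must be >= 1", "abl1kd_validation_error")
  }
  out <- lapply(0:n_dilutions, function(k) {
    spikes_k <- if (is.null(base_spikes)) NULL else
      mutate(base_spikes, target_vaf = .data$target_vaf / 2^k)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    simulate_sample(panel, spikes_k, cfg, sample_id = sprintf("%s_D%d", sample_id, k))
  })
  setNames(out, sprintf("D%d", 0:n_dilutions))
}

#' Simulate replicate libraries of one sample
#'
#' Replicates share identical truth VAFs but independent sampling noise;
#' per-replicate seeds are derived deterministically from `config$seed`.
#'
#' @inheritParams simulate_sample
#' @param n_reps Number of replicates (>= 2).
#' @return List of `simulate_sample()` results, names `"R1"`..`"Rn"`.
#' @export
simulate_replicates <- function(panel, spikes, n_reps = 2, config = sim_config(),
                                sample_id = "replicate") {
  if (n_reps < 2) {
    abort_abl1kd("n_reps must be >= 2", "abl1kd_validation_error")
  }
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100000 + r)
    simulate_sample(panel, spikes, cfg, sample_id = sprintf("%s_R%d", sample_id, r))
  })
  setNames(out, sprintf("R%d", seq_len(n_reps)))
}

#' Simulate a multi-sample cohort
#'
#' @inheritParams simulate_sample
#' @param spec Cohort spec tibble (columns `sample_id`, `protein_change`,
#'   `target_vaf`; negative samples have `NA` in both spike columns), e.g.
#'   [default_cohort_spec()].
#' @return Named list (one element per sample) of `simulate_sample()` results.
#' @export
simulate_cohort <- function(panel, spec, config = sim_config()) {
  if (is.null(spec) || nrow(spec) == 0) {
    abort_abl1kd("cohort spec must contain at least one sample", "abl1kd_validation_error")
  }
  ids <- unique(spec$sample_id)
  out <- lapply(seq_along(ids), function(i) {
    rows <- filter(spec, .data$sample_id == ids[i], !is.na(.data$protein_change))
    spikes <- if (nrow(rows) > 0) {
      spike_spec(rows$protein_change, rows$target_vaf)
    } else NULL
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 200000 + i)
    simulate_sample(panel, spikes, cfg, sample_id = ids[i])
  })
  setNames(out, ids)
}

#' The packaged default cohort spec
#'
#' A 121-sample cohort emulating the study population's mutation spectrum:
#' 42 positive samples carrying 63 variants in total (14 T315I, 10 F317L,
#' 8 L248V, down to six singleton variants), nine samples with compound
#' (>= 2) mutations, and spike VAFs spanning 2.3-93.41%.
#'
#' @param path Optional path to a cohort spec YAML; defaults to the packaged
#'   one.
#' @return Tibble with columns `sample_id`, `protein_change`, `target_vaf`
#'   (one row per spike; negative samples have one all-`NA` spike row).
#' @export
default_cohort_spec <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cohort_spec_default.yaml", package = "abl1kd")
  read_cohort_spec(path)
}

#' Read / write a cohort spec YAML
#'
#' @param path YAML path.
#' @return `read_cohort_spec()` returns the spec tibble; `write_cohort_spec()`
#'   returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$samples, function(s) {
    if (length(s$spikes) == 0) {
      tibble(sample_id = s$id, protein_change = NA_character_, target_vaf = NA_real_)
    } else {
      tibble(
        sample_id = s$id,
        protein_change = vapply(s$spikes, function(v) v$change, character(1)),
        target_vaf = vapply(s$spikes, function(v) as.numeric(v$vaf), numeric(1))
      )
    }
  })
  bind_rows(rows)
}

#' @rdname read_cohort_spec
#' @param spec A cohort spec tibble.
#' @export
write_cohort_spec <- function(spec, path) {
  samples <- lapply(unique(spec$sample_id), function(id) {
    rows <- filter(spec, .data$sample_id == id, !is.na(.data$protein_change))
    list(
      id = id,
      spikes = lapply(seq_len(nrow(rows)), function(i) {
        list(change = rows$protein_change[i], vaf = rows$target_vaf[i])
      })
    )
  })
  yaml::write_yaml(list(samples = samples), path)
  invisible(path)
}

#' Write / read simulated reads as FASTQ
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param path FASTQ path (".gz" suffix enables compression).
#' @param quality_char Constant Phred+33 symbol for every base.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   reads tibble.
#' @export
write_fastq <- function(reads, path, quality_char = "?") {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = unname(as.character(x)))
}

#' Write / read a truth record's spike table as TSV
#'
#' @param truth A `kd_truth` (from [simulate_sample()]) or a list of them.
#' @param path TSV path.
#' @return `write_truth_tsv()` returns `path` invisibly; `read_truth_tsv()`
#'   returns the spike tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  if (inherits(truth, "kd_truth")) truth <- list(truth)
  tbl <- bind_rows(lapply(truth, function(t) t$spikes))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), protein_change = readr::col_character(),
    kd_pos = readr::col_integer(), ref_base = readr::col_character(),
    alt_base = readr::col_character(), target_vaf = readr::col_double(),
    alt_reads = readr::col_integer(), covering_reads = readr::col_integer()
  ))
}
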