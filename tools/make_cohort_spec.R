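# Generates inst/extdata/cohort_spec_default.yaml: a 121-sample cohort with
# 42 positives, 63 spiked variants (14 T315I, 10 F317L, 8 L248V, ...), nine
# compound samples, and VAFs spanning 2.3-93.41%. Deterministic (fixed seed).
suppressMessages(devtools::load_all(".", quiet = TRUE))

spectrum <- c(
  T315I = 14, F317L = 10, L248V = 8, G250E = 6, M244V = 4, F359V = 4,
  E255K = 3, E255V = 3, M351T = 3, H396P = 1, F359C = 1, E355G = 1,
  E459K = 1, H396R = 1, L387M = 1, Y253F = 1, Y253H = 1
)
stopifnot(sum(spectrum) == 63)

known <- list(
  S001 = list(c("T315I", 17.76), c("F359V", 63.43)),
  S004 = list(c("G250E", 52.01), c("M244V", 5.01), c("E255V", 3.14)),
  S016 = list(c("F359C", 34.67), c("F317L", 11.83), c("E255V", 11.4), c("G250E", 4.08)),
  S017 = list(c("T315I", 31.17), c("G250E", 57.24))
)
invented_compounds <- list(
  S002 = c("T315I", "F317L", "L248V", "E255K"),
  S003 = c("T315I", "F317L", "L248V", "M351T"),
  S005 = c("T315I", "G250E", "M244V", "E459K"),
  S006 = c("F317L", "L248V", "F359V", "E255V"),
  S007 = c("T315I", "L248V", "E355G")
)

pool <- spectrum
for (s in known) for (v in s) pool[v[1]] <- pool[v[1]] - 1
for (s in invented_compounds) for (v in s) pool[v] <- pool[v] - 1
stopifnot(all(pool >= 0), sum(pool) == 33)

singles <- rep(names(pool), pool)
set.seed(20240708)
singles <- sample(singles)

rows <- list()
add <- function(id, change, vaf) {
  rows[[length(rows) + 1]] <<- tibble::tibble(
    sample_id = id, protein_change = change, target_vaf = vaf
  )
}
for (id in names(known)) for (v in known[[id]]) add(id, v[[1]], as.numeric(v[[2]]))
for (id in names(invented_compounds)) {
  changes <- invented_compounds[[id]]
  vafs <- c(round(runif(1, 25, 80), 2), round(runif(length(changes) - 1, 2.5, 20), 2))
  for (i in seq_along(changes)) add(id, changes[i], vafs[i])
}
single_ids <- sprintf("S%03d", setdiff(1:42, as.integer(sub("S", "", c(names(known), names(invented_compounds))))))
stopifnot(length(single_ids) == 33)
vafs <- round(runif(33, 2.5, 93), 2)
# pin the cohort's VAF range: smallest 2.3%, largest 93.41%
t315i_singles <- which(singles == "T315I")
vafs[t315i_singles[1]] <- 2.3
vafs[t315i_singles[2]] <- 93.41
for (i in seq_along(single_ids)) add(single_ids[i], singles[i], vafs[i])
for (i in 43:121) add(sprintf("S%03d", i), NA_character_, NA_real_)

spec <- dplyr::bind_rows(rows)

# --- invariants ---------------------------------------------------------
pos <- dplyr::filter(spec, !is.na(protein_change))
stopifnot(length(unique(spec$sample_id)) == 121)
stopifnot(length(unique(pos$sample_id)) == 42)
stopifnot(nrow(pos) == 63)
counts <- table(pos$protein_change)
stopifnot(all(counts[names(spectrum)] == spectrum))
n_per <- table(pos$sample_id)
stopifnot(sum(n_per >= 2) == 9, max(n_per) == 4)
stopifnot(min(pos$target_vaf) == 2.3, max(pos$target_vaf) == 93.41)
# no duplicate change within a sample
stopifnot(!any(duplicated(paste(pos$sample_id, pos$protein_change))))
# every spike resolvable against surrogates built under different seeds
for (s in c(1, 99)) {
  ref <- build_surrogate_reference(hotspot_catalogue(), seed = s)
  resolved <- abl1kd:::resolve_spikes(
    spike_spec(unique(pos$protein_change), 10), ref
  )
  stopifnot(nrow(resolved) == length(unique(pos$protein_change)))
}

write_cohort_spec(spec, "inst/extdata/cohort_spec_default.yaml")
back <- read_cohort_spec("inst/extdata/cohort_spec_default.yaml")
stopifnot(identical(as.data.frame(spec), as.data.frame(back)))
cat("cohort spec written:", nrow(spec), "rows\n")
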