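# Shared fixtures, built once per test run.

CAT <- hotspot_catalogue()
REF <- build_surrogate_reference(CAT, seed = 1)
PANEL <- build_amplicon_panel(REF, seed = 1)

# site coverage multiplicity: number of amplicon non-primer interiors
# containing a KD position
site_multiplicity <- function(panel, pos) {
  sum(panel$start + panel$fwd_primer_len <= pos &
        pos < panel$end - panel$rev_primer_len)
}

# reads_total that puts ~`depth` reads over a given site
reads_for_depth <- function(panel, pos, depth = 2000) {
  m <- site_multiplicity(panel, pos)
  as.integer(nrow(panel) * depth / m)
}

# resolved spike position of a protein change under REF
spike_pos <- function(change, ref = REF) {
  abl1kd:::resolve_spikes(spike_spec(change, 50), ref)$kd_pos
}

# 4-binomial-SD band around a truth VAF (percent) at a given depth
vaf_within_4sd <- function(observed, truth, depth) {
  p <- truth / 100
  sd_pct <- 100 * sqrt(p * (1 - p) / depth)
  abs(observed - truth) <= 4 * sd_pct
}

# small QC thresholds for desk-scale libraries
QC_TINY <- qc_thresholds(min_total_reads = 100, min_on_target = 0.99)
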