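#' Loss-calling thresholds
#'
#' Bundle of the numeric thresholds used throughout the pipeline. The
#' defaults are the values the loss screen was designed around: a gene is
#' called lost when less than 60% of the reading frame remains intact and at
#' least 20% of its exons carry inactivating mutations (single-exon genes:
#' at least two inactivating mutations); a mutation is confirmed by reads
#' when at least five reads support it and none supports the ancestral
#' allele, using 50 bp of flanking sequence; an unaligned exon overlapping a
#' run of at least `min_gap_run` N characters is treated as missing data
#' (assembly gap), not as a deletion.
#'
#' @param max_intact_fraction loss requires intact fraction strictly below
#'   this value (default 0.60).
#' @param min_exon_fraction_hit loss requires at least this fraction of
#'   (non-missing) exons to carry an inactivating mutation (default 0.20).
#' @param min_mutations_single_exon minimum number of inactivating mutations
#'   for a single-exon gene to be called lost (default 2).
#' @param min_supporting_reads reads required to confirm a mutation
#'   (default 5).
#' @param flank_bp flanking sequence extracted around a mutation for read
#'   validation (default 50).
#' @param min_gap_run minimum run of N characters interpreted as an assembly
#'   gap (default 10).
#' @return an object of class `loss_thresholds`.
#' @export
loss_thresholds <- function(max_intact_fraction = 0.60,
                            min_exon_fraction_hit = 0.20,
                            min_mutations_single_exon = 2L,
                            min_supporting_reads = 5L,
                            flank_bp = 50L,
                            min_gap_run = 10L) {
  th <- list(max_intact_fraction = as.numeric(max_intact_fraction),
             min_exon_fraction_hit = as.numeric(min_exon_fraction_hit),
             min_mutations_single_exon = as.integer(min_mutations_single_exon),
             min_supporting_reads = as.integer(min_supporting_reads),
             flank_bp = as.integer(flank_bp),
             min_gap_run = as.integer(min_gap_run))
  for (nm in names(th)) {
    v <- th[[nm]]
    if (length(v) != 1L || is.na(v) || v <= 0)
      stopf("threshold '%s' must be a single strictly positive value", nm)
  }
  structure(th, class = "loss_thresholds")
}
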