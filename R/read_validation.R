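# Validation of candidate inactivating mutations against unassembled reads.
#
# For each mutation, 50 bp of genomic sequence up- and downstream are
# extracted around the assembly (mutant) allele, and a second context is
# built with the ancestral (non-inactivating) allele substituted. Each read
# is aligned gap-aware against both contexts (both strands); a read
# supports the haplotype to which it aligns with strictly fewer
# mismatches+gaps, provided the alignment covers the variant position and
# stays within the identity tolerance. A mutation is confirmed when at
# least five reads support it and no read supports the ancestral allele.

#' Extract mutant and ancestral context around a mutation
#'
#' @param contig query contig sequence (single string).
#' @param pos 1-based position of the first base of the query allele on the
#'   contig (for a pure deletion, the first base after the deletion).
#' @param ref_allele ancestral allele as in the mutation table (`"-"` or
#'   `""` for a pure insertion's reference side).
#' @param query_allele assembly allele (`"-"` or `""` for a deletion).
#' @param flank_bp flanking bases on each side (default 50).
#' @return list with `mutant`/`ancestral` context strings, the 1-based
#'   inclusive span (`mutant_var`, `ancestral_var`) that an informative
#'   read must cover in each context (the variant plus one anchoring base
#'   each side), and `truncated_upstream`/`truncated_downstream` flags set
#'   when a contig edge shortened a flank.
#' @export
extract_context <- function(contig, pos, ref_allele, query_allele,
                            flank_bp = 50L) {
  q <- gsub("-", "", query_allele, fixed = TRUE)
  r <- gsub("-", "", ref_allele, fixed = TRUE)
  len <- nchar(contig)
  if (pos < 1L || pos + nchar(q) - 1L > len)
    stopf("mutation position %d outside contig (length %d)", pos, len)
  up_start <- max(1L, pos - flank_bp)
  down_start <- pos + nchar(q)
  down_end <- min(len, down_start + flank_bp - 1L)
  up <- substr(contig, up_start, pos - 1L)
  down <- if (down_start <= len) substr(contig, down_start, down_end) else ""
  mutant <- paste0(up, q, down)
  ancestral <- paste0(up, r, down)
  span <- function(allele_len)
    c(max(1L, nchar(up)), min(nchar(up) + allele_len + 1L,
                              nchar(up) + allele_len + nchar(down)))
  list(mutant = tolower(mutant), ancestral = tolower(ancestral),
       mutant_var = span(nchar(q)), ancestral_var = span(nchar(r)),
       truncated_upstream = nchar(up) < flank_bp,
       truncated_downstream = nchar(down) < flank_bp)
}

# best (min-edit) semi-global alignment of a read against a context,
# trying both orientations; returns edits and covered span
best_alignment <- function(read, context) {
  f <- semi_global_edits(read, context)
  r <- semi_global_edits(revcomp(read), context)
  if (r[1L] < f[1L]) r else f
}

#' Tally read support for a mutation
#'
#' Assigns each read to the mutant or ancestral haplotype (or neither) and
#' applies the confirmation rule: `CONFIRMED` requires at least
#' `thresholds$min_supporting_reads` supporting reads and zero ancestral
#' reads; no informative reads at all gives `NO_DATA`. A read is
#' informative for a context when its best gap-aware alignment covers the
#' variant span, has at most `max_edit_rate` edits per aligned base, and
#' has strictly fewer edits than the alignment to the other context; equal
#' edit counts are uninformative. Reads matching neither context (e.g.
#' contaminants) are uninformative. Verdicts are invariant under read
#' order.
#'
#' @param contexts result of [extract_context()].
#' @param reads character vector of read sequences (or a path to a
#'   FASTA/FASTQ file, read via [read_reads()]).
#' @param thresholds a [loss_thresholds()].
#' @param max_edit_rate maximum edits per aligned base (default 0.02,
#'   approximating megablast-level identity).
#' @return data.frame with `n_supporting`, `n_ancestral`,
#'   `n_uninformative`, `status`.
#' @export
tally_support <- function(contexts, reads,
                          thresholds = loss_thresholds(),
                          max_edit_rate = 0.02) {
  if (is_string(reads) && file.exists(reads)) reads <- read_reads(reads)
  n_sup <- 0L; n_anc <- 0L; n_un <- 0L
  for (rd in reads) {
    rd <- tolower(rd)
    allowed <- floor(max_edit_rate * nchar(rd) + 1e-9)
    am <- best_alignment(rd, contexts$mutant)
    aa <- best_alignment(rd, contexts$ancestral)
    ok_m <- am[1L] <= allowed && am[2L] <= contexts$mutant_var[1L] &&
      am[3L] >= contexts$mutant_var[2L]
    ok_a <- aa[1L] <= allowed && aa[2L] <= contexts$ancestral_var[1L] &&
      aa[3L] >= contexts$ancestral_var[2L]
    score_m <- if (ok_m) am[1L] else Inf
    score_a <- if (ok_a) aa[1L] else Inf
    if (score_m < score_a) n_sup <- n_sup + 1L
    else if (score_a < score_m) n_anc <- n_anc + 1L
    else n_un <- n_un + 1L
  }
  status <- if (n_sup + n_anc == 0L) "NO_DATA"
  else if (n_sup >= thresholds$min_supporting_reads && n_anc == 0L)
    "CONFIRMED"
  else "UNCONFIRMED"
  data.frame(n_supporting = n_sup, n_ancestral = n_anc,
             n_uninformative = n_un, status = status,
             stringsAsFactors = FALSE)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path file path (format decided by extension: .fq/.fastq are
#'   FASTQ, everything else FASTA).
#' @return named character vector of read sequences (lower case).
#' @export
read_reads <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("fq", "fastq"))
    Biostrings::readDNAStringSet(path, format = "fastq")
  else Biostrings::readDNAStringSet(path)
  stats::setNames(tolower(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Validate a table of mutation loci against read sets
#'
#' @param loci data.frame with columns `locus_id`, `contig_id`, `pos`,
#'   `ref_allele`, `query_allele` (as written by the synthetic generator's
#'   `validation_loci.tsv`).
#' @param contigs named character vector of contig sequences (or FASTA
#'   path).
#' @param reads_dir directory containing `<locus_id>.fastq` files.
#' @param thresholds a [loss_thresholds()].
#' @return `loci` with the tally columns and `status` appended.
#' @export
validate_mutations <- function(loci, contigs, reads_dir,
                               thresholds = loss_thresholds()) {
  if (is_string(contigs) && file.exists(contigs))
    contigs <- read_fasta(contigs)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    ctx <- extract_context(contigs[[l$contig_id]], l$pos, l$ref_allele,
                           l$query_allele, thresholds$flank_bp)
    fq <- file.path(reads_dir, paste0(l$locus_id, ".fastq"))
    reads <- if (file.exists(fq)) read_reads(fq) else character(0)
    cbind(l, tally_support(ctx, reads, thresholds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
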