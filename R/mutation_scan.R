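# Detection of gene-inactivating mutations in per-exon pairwise alignments.
#
# Mutation classes: premature stop codons, frameshifting insertions and
# deletions (gap runs whose length is not a multiple of 3), splice-site
# disruptions (query donor not GT/GC, query acceptor not AG), deletion of
# whole exons and of whole genes. Unaligned exons whose query interval
# contains a long N run are assembly gaps (missing data), not deletions.
#
# Frame convention: codons are read in the REFERENCE frame. Alignment
# columns where the reference row is gapped (query insertions) are excised
# before codon reading, and query deletions leave '-' placeholders at the
# deleted reference positions. This deliberately avoids cascades of
# spurious stop codons downstream of a frameshift: a frameshift and any
# genuine stop-codon mutation are counted as independent events.
# Compensatory indel pairs each count separately (no net-frame forgiveness).

MUTATION_KINDS <- c("PREMATURE_STOP", "FRAMESHIFT_INS", "FRAMESHIFT_DEL",
                    "SPLICE_DONOR", "SPLICE_ACCEPTOR", "EXON_DELETED",
                    "GENE_DELETED")
STOP_CODONS <- c("taa", "tag", "tga")

# canonical empty mutation table
empty_mutations <- function() {
  data.frame(kind = character(0), exon_index = integer(0),
             codon_position = integer(0), ref_allele = character(0),
             query_allele = character(0), indel_length = integer(0),
             stringsAsFactors = FALSE)
}

mutation_row <- function(kind, exon_index, codon_position, ref_allele,
                         query_allele, indel_length = NA_integer_) {
  data.frame(kind = kind, exon_index = as.integer(exon_index),
             codon_position = as.integer(codon_position),
             ref_allele = ref_allele, query_allele = query_allele,
             indel_length = as.integer(indel_length),
             stringsAsFactors = FALSE)
}

# deterministic output order: (exon_index, codon_position, kind), NAs last
sort_mutations <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order_na_last(df$exon_index, df$codon_position, df$kind), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# organize a read_exon_alignments() result (or any list of exon_alignment
# records) into a per-exon list for one transcript
alignments_for_transcript <- function(alignments, model) {
  n <- nrow(model$exons)
  out <- vector("list", n)
  for (rec in alignments) {
    if (!is.null(rec) && rec$transcript_id == model$transcript_id)
      out[[rec$exon_index + 1L]] <- rec
  }
  out
}

# split a flat record list into per-transcript per-exon lists
split_alignments <- function(alignments, models) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (m in models)
    assign(m$transcript_id, vector("list", nrow(m$exons)), envir = env)
  for (rec in alignments) {
    cur <- get0(rec$transcript_id, envir = env)
    if (is.null(cur)) next
    cur[[rec$exon_index + 1L]] <- rec
    assign(rec$transcript_id, cur, envir = env)
  }
  env
}

#' Classify an unaligned exon as deleted or missing
#'
#' Distinguishes real exon deletions from assembly gaps: an unaligned exon
#' whose query syntenic interval contains a run of at least
#' `thresholds$min_gap_run` N characters — or whose interval cannot be
#' resolved at all (`NA`) — is missing data; an unaligned exon with a
#' gap-free query interval is a genuine deletion.
#'
#' @param context query sequence spanning the syntenic interval of the
#'   unaligned exon, or `NA` when unresolvable.
#' @param thresholds a [loss_thresholds()].
#' @return `"DELETED"` or `"MISSING"`.
#' @export
classify_exon_status <- function(context, thresholds = loss_thresholds()) {
  if (is.na(context)) return("MISSING")
  pat <- sprintf("[nN]{%d,}", thresholds$min_gap_run)
  if (grepl(pat, context)) "MISSING" else "DELETED"
}

# per-exon status vector for one transcript: ALIGNED where a record exists,
# otherwise DELETED/MISSING via the context table
exon_statuses <- function(model, exon_alns, contexts = NULL,
                          thresholds = loss_thresholds()) {
  n <- nrow(model$exons)
  if (is.character(contexts))
    contexts <- list2env(as.list(contexts), hash = TRUE)
  status <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(exon_alns[[i]])) { status[i] <- "ALIGNED"; next }
    key <- sprintf("%s:%d", model$transcript_id, i - 1L)
    ctx <- if (!is.null(contexts)) get0(key, envir = contexts,
                                        ifnotfound = NA_character_)
    else NA_character_
    if (is.null(ctx)) ctx <- NA_character_
    status[i] <- classify_exon_status(ctx, thresholds)
  }
  status
}

# query CDS in the reference frame: list(ref = char vector, query = char
# vector), both of length cds_length; query has '-' at deleted positions and
# 'n' at positions of missing exons
spliced_cds <- function(model, exon_alns, status) {
  n <- nrow(model$exons)
  len <- model$exons[, "end"] - model$exons[, "start"]
  refs <- vector("list", n); qrys <- vector("list", n)
  for (i in seq_len(n)) {
    if (status[i] == "ALIGNED") {
      rc <- chars(exon_alns[[i]]$ref_aln)
      qc <- chars(exon_alns[[i]]$query_aln)
      keep <- rc != "-"                       # excise query insertions
      refs[[i]] <- rc[keep]
      qrys[[i]] <- qc[keep]
    } else {
      refs[[i]] <- rep("?", len[i])
      qrys[[i]] <- rep(if (status[i] == "DELETED") "-" else "n", len[i])
    }
  }
  list(ref = unlist(refs), query = unlist(qrys))
}

#' Detect premature stop codons
#'
#' Reads the query coding sequence codon by codon in the reference frame
#' (insertions excised, deletions as gaps; codons are read across exon
#' junctions on the spliced sequence) and reports every reference codon
#' position at which the query carries TAA/TAG/TGA while the reference does
#' not. The natural terminal stop codon is never reported, and any codon
#' containing a gap or N on the query side is skipped (frameshift and
#' missing-data logic handle those).
#'
#' @param model a [gene_model()].
#' @param exon_alns per-exon list of alignment records (see
#'   [read_exon_alignments()]); `NULL` entries are treated as non-aligned.
#' @param status optional per-exon status vector; computed from `exon_alns`
#'   when omitted.
#' @return mutation data.frame (kind, exon_index, codon_position,
#'   ref_allele, query_allele, indel_length).
#' @export
detect_premature_stops <- function(model, exon_alns, status = NULL) {
  if (is.null(status))
    status <- ifelse(vapply(exon_alns, is.null, logical(1L)),
                     "MISSING", "ALIGNED")
  cds <- spliced_cds(model, exon_alns, status)
  L <- n_codons(model)
  if (L < 2L) return(empty_mutations())
  rmat <- matrix(cds$ref, nrow = 3L)
  qmat <- matrix(cds$query, nrow = 3L)
  rcod <- paste0(rmat[1L, ], rmat[2L, ], rmat[3L, ])
  qcod <- paste0(qmat[1L, ], qmat[2L, ], qmat[3L, ])
  idx <- seq_len(L - 1L)                     # terminal stop excluded
  hit <- idx[qcod[idx] %in% STOP_CODONS &
               !grepl("[-n?]", qcod[idx]) &
               qcod[idx] != rcod[idx]]
  if (!length(hit)) return(empty_mutations())
  off <- exon_offsets(model)
  exon_of_codon <- function(c1) {
    # exon containing the first base of codon c1 (0-based exon index)
    p <- (c1 - 1L) * 3L
    findInterval(p, off[-length(off)])- 1L
  }
  do.call(rbind, lapply(hit, function(c1)
    mutation_row("PREMATURE_STOP", exon_of_codon(c1), c1,
                 rcod[c1], qcod[c1])))
}

#' Detect frameshifting insertions and deletions
#'
#' Every maximal run of gap characters in either alignment row whose length
#' is not a multiple of 3 yields one mutation: `FRAMESHIFT_DEL` for a
#' query-side gap (bases deleted from the query), `FRAMESHIFT_INS` for a
#' reference-side gap (bases inserted in the query). In-frame (length 3k)
#' indels are ignored. Adjacent insertion and deletion runs are separate
#' events; compensatory pairs are both reported. The reported codon is the
#' reference codon overlapping the start of the run.
#'
#' @inheritParams detect_premature_stops
#' @return mutation data.frame.
#' @export
detect_frameshifts <- function(model, exon_alns, status = NULL) {
  if (is.null(status))
    status <- ifelse(vapply(exon_alns, is.null, logical(1L)),
                     "MISSING", "ALIGNED")
  off <- exon_offsets(model)
  out <- list()
  for (i in seq_len(nrow(model$exons))) {
    if (status[i] != "ALIGNED") next
    rc <- chars(exon_alns[[i]]$ref_aln)
    qc <- chars(exon_alns[[i]]$query_aln)
    ref_before <- cumsum(c(0L, head(rc != "-", -1L)))  # ref bases before col
    for (side in c("del", "ins")) {
      gap <- if (side == "del") qc == "-" else rc == "-"
      if (!any(gap)) next
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths %% 3L != 0L)
      for (k in runs) {
        s <- starts[k]; e <- ends[k]
        if (side == "del") {
          p <- off[i] + ref_before[s] + 1L          # first deleted ref base
          codon <- (p + 2L) %/% 3L
          ref_allele <- paste(rc[s:e], collapse = "")
          query_allele <- "-"
        } else {
          p0 <- off[i] + ref_before[s]              # ref base before run
          codon <- max(1L, (p0 + 2L) %/% 3L)
          ref_allele <- "-"
          query_allele <- paste(qc[s:e], collapse = "")
        }
        out[[length(out) + 1L]] <- mutation_row(
          if (side == "del") "FRAMESHIFT_DEL" else "FRAMESHIFT_INS",
          i - 1L, codon, ref_allele, query_allele, e - s + 1L)
      }
    }
  }
  if (!length(out)) return(empty_mutations())
  do.call(rbind, out)
}

#' Detect splice-site disruptions
#'
#' A donor dinucleotide deviating from GT/GC, or an acceptor deviating from
#' AG (case-insensitive), is an inactivating mutation. Dinucleotides
#' containing N are missing data and are not called. Single-exon genes have
#' no splice sites. The reported codon is the exon-boundary codon adjacent
#' to the disrupted site.
#'
#' @inheritParams detect_premature_stops
#' @return mutation data.frame.
#' @export
detect_splice_mutations <- function(model, exon_alns, status = NULL) {
  n <- nrow(model$exons)
  if (n < 2L) return(empty_mutations())
  if (is.null(status))
    status <- ifelse(vapply(exon_alns, is.null, logical(1L)),
                     "MISSING", "ALIGNED")
  off <- exon_offsets(model)
  out <- list()
  for (i in seq_len(n)) {
    if (status[i] != "ALIGNED") next
    rec <- exon_alns[[i]]
    if (i < n && !is.na(rec$query_donor)) {
      d <- tolower(rec$query_donor)
      if (!grepl("n", d) && !d %in% c("gt", "gc")) {
        codon <- (off[i + 1L] + 2L) %/% 3L      # last codon of exon i
        out[[length(out) + 1L]] <- mutation_row(
          "SPLICE_DONOR", i - 1L, codon,
          tolower(if (is.na(rec$ref_donor)) "gt" else rec$ref_donor), d)
      }
    }
    if (i > 1L && !is.na(rec$query_acceptor)) {
      a <- tolower(rec$query_acceptor)
      if (!grepl("n", a) && a != "ag") {
        codon <- off[i] %/% 3L + 1L             # first codon of exon i
        out[[length(out) + 1L]] <- mutation_row(
          "SPLICE_ACCEPTOR", i - 1L, codon,
          tolower(if (is.na(rec$ref_acceptor)) "ag" else rec$ref_acceptor), a)
      }
    }
  }
  if (!length(out)) return(empty_mutations())
  do.call(rbind, out)
}

#' Scan one transcript of one query species for inactivating mutations
#'
#' Combines all detectors: exon statuses are resolved first (aligned /
#' deleted / missing); if every exon is deleted a single whole-gene
#' deletion is reported; otherwise each deleted exon yields an exon
#' deletion event, and aligned exons are scanned for premature stops,
#' frameshifts and splice-site disruptions. Output rows are sorted by
#' (exon_index, codon_position, kind).
#'
#' @param model a [gene_model()].
#' @param alignments list of exon alignment records (e.g. from
#'   [read_exon_alignments()]); records for other transcripts are ignored.
#' @param contexts query-context vector from [read_contexts()] (used to
#'   separate deletions from assembly gaps for unaligned exons).
#' @param thresholds a [loss_thresholds()].
#' @return list with `mutations` (data.frame) and `status` (per-exon
#'   character vector).
#' @export
scan_transcript <- function(model, alignments, contexts = NULL,
                            thresholds = loss_thresholds()) {
  exon_alns <- alignments_for_transcript(alignments, model)
  scan_transcript_exons(model, exon_alns, contexts, thresholds)
}

scan_transcript_exons <- function(model, exon_alns, contexts = NULL,
                                  thresholds = loss_thresholds()) {
  status <- exon_statuses(model, exon_alns, contexts, thresholds)
  n <- nrow(model$exons)
  if (all(status == "DELETED")) {
    mut <- mutation_row("GENE_DELETED", NA_integer_, NA_integer_, "+", "-")
    return(list(mutations = mut, status = status))
  }
  muts <- list(detect_premature_stops(model, exon_alns, status),
               detect_frameshifts(model, exon_alns, status),
               detect_splice_mutations(model, exon_alns, status))
  del <- which(status == "DELETED")
  if (length(del))
    muts[[length(muts) + 1L]] <- do.call(rbind, lapply(del, function(i)
      mutation_row("EXON_DELETED", i - 1L, NA_integer_, "+", "-")))
  df <- sort_mutations(do.call(rbind, muts))
  list(mutations = df, status = status)
}

#' Scan all transcripts of one species
#'
#' @param models list of [gene_model()] objects.
#' @param alignments result of [read_exon_alignments()] for one species.
#' @param contexts result of [read_contexts()] for the same species.
#' @param species species name (added to the output rows).
#' @param thresholds a [loss_thresholds()].
#' @return list with `mutations` (one data.frame with gene/transcript/
#'   species columns prepended, the machine-readable per-exon mutation map)
#'   and `statuses` (named list of per-exon status vectors).
#' @export
scan_species <- function(models, alignments, contexts = NULL,
                         species = "query",
                         thresholds = loss_thresholds()) {
  if (is.character(contexts))
    contexts <- list2env(as.list(contexts), hash = TRUE)
  by_tx <- split_alignments(alignments, models)
  tabs <- list(); stats_ <- list()
  for (m in models) {
    res <- scan_transcript_exons(m, get0(m$transcript_id, envir = by_tx),
                                 contexts, thresholds)
    stats_[[m$transcript_id]] <- res$status
    if (nrow(res$mutations)) {
      df <- cbind(data.frame(gene_id = m$gene_id,
                             transcript_id = m$transcript_id,
                             species = species,
                             stringsAsFactors = FALSE),
                  res$mutations)
      tabs[[length(tabs) + 1L]] <- df
    }
  }
  mut <- if (length(tabs)) do.call(rbind, tabs) else
    cbind(data.frame(gene_id = character(0), transcript_id = character(0),
                     species = character(0), stringsAsFactors = FALSE),
          empty_mutations())
  rownames(mut) <- NULL
  list(mutations = mut, statuses = stats_)
}
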