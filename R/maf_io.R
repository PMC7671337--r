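# Pairwise coding-exon alignments: MAF ingestion and emission.
#
# Contract: every alignment block covers exactly one coding exon of one
# reference gene model, extended by 2 bp of flanking intron on each side
# that has a splice boundary (acceptor side for non-first exons, donor side
# for non-last exons). The flank columns must be ungapped in the reference
# row; the reader strips them into the query acceptor/donor dinucleotide
# fields of the resulting exon alignment. Rows are written in transcription
# orientation; MAF ingestion is supported for plus-strand reference models
# (minus-strand models are handled at the BED/GTF/FASTA level).

#' Read raw MAF blocks
#'
#' Parses a pairwise MAF file into one row per block. Each block must have
#' exactly two `s` rows: the reference first, the query second.
#'
#' @param path MAF file.
#' @return data.frame with reference and query `src`, `start`, `size`,
#'   `strand`, `srcsize` and alignment `text` columns.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  a_idx <- grep("^a", lines)
  s_idx <- grep("^s ", lines)
  if (!length(a_idx)) stopf("no alignment blocks in %s", path)
  block_of <- findInterval(s_idx, a_idx)
  if (any(tabulate(block_of, length(a_idx)) != 2L))
    stopf("each MAF block in %s must have exactly two 's' rows", path)
  f <- strsplit(lines[s_idx], "[ \t]+")
  if (any(lengths(f) != 7L))
    stopf("malformed 's' row in %s", path)
  m <- do.call(rbind, f)
  ref <- seq(1L, length(s_idx), by = 2L)
  qry <- ref + 1L
  out <- data.frame(
    ref_src = m[ref, 2L], ref_start = as.integer(m[ref, 3L]),
    ref_size = as.integer(m[ref, 4L]), ref_strand = m[ref, 5L],
    ref_srcsize = as.integer(m[ref, 6L]), ref_text = m[ref, 7L],
    q_src = m[qry, 2L], q_start = as.integer(m[qry, 3L]),
    q_size = as.integer(m[qry, 4L]), q_strand = m[qry, 5L],
    q_srcsize = as.integer(m[qry, 6L]), q_text = m[qry, 7L],
    stringsAsFactors = FALSE)
  bad <- nchar(out$ref_text) != nchar(out$q_text)
  if (any(bad))
    stopf("MAF row length mismatch in block %d of %s", which(bad)[1L], path)
  out
}

#' Write MAF blocks
#'
#' @param blocks data.frame as returned by [read_maf()].
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  per <- paste0("a score=0\n",
                sprintf("s %s %d %d %s %d %s\n", blocks$ref_src,
                        blocks$ref_start, blocks$ref_size, blocks$ref_strand,
                        blocks$ref_srcsize, blocks$ref_text),
                sprintf("s %s %d %d %s %d %s\n", blocks$q_src,
                        blocks$q_start, blocks$q_size, blocks$q_strand,
                        blocks$q_srcsize, blocks$q_text),
                "\n")
  writeLines(c("##maf version=1\n\n", per), path, sep = "")
  invisible(path)
}

# internal constructor for one exon alignment record
exon_alignment <- function(gene_id, transcript_id, exon_index, species,
                           status, ref_aln = NA_character_,
                           query_aln = NA_character_,
                           query_donor = NA_character_,
                           query_acceptor = NA_character_,
                           ref_donor = NA_character_,
                           ref_acceptor = NA_character_) {
  if (status == "ALIGNED") {
    if (nchar(ref_aln) != nchar(query_aln))
      stopf("aligned rows differ in length (%s exon %d)",
            transcript_id, exon_index)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 exon_index = as.integer(exon_index), species = species,
                 status = status, ref_aln = ref_aln, query_aln = query_aln,
                 query_donor = query_donor, query_acceptor = query_acceptor,
                 ref_donor = ref_donor, ref_acceptor = ref_acceptor),
            class = "exon_alignment")
}

#' Read per-exon alignments for one query species
#'
#' Maps MAF blocks onto the coding exons of the supplied gene models and
#' returns one record per aligned exon. Exons without any block are simply
#' absent from the result; whether they are deleted or lie in an assembly
#' gap is decided downstream by [classify_exon_status()] using the query
#' context table. The species name is taken from the query row `src`
#' (portion before the first '.').
#'
#' @param path MAF file with exactly one query species.
#' @param models list of [gene_model()] objects.
#' @return named list of `exon_alignment` records, names
#'   `transcript_id:exon_index` (0-based exon index).
#' @export
read_exon_alignments <- function(path, models) {
  blocks <- read_maf(path)
  species <- unique(sub("\\..*$", "", blocks$q_src))
  if (length(species) != 1L)
    stopf("%s contains %d query species; expected exactly one",
          path, length(species))
  # lookup: extended ref span -> (model index, exon index)
  map <- new.env(hash = TRUE, parent = emptyenv())
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    if (m$strand != "+")
      stopf("MAF ingestion supports plus-strand reference models (%s)",
            m$transcript_id)
    n <- nrow(m$exons)
    for (i in seq_len(n)) {
      al <- if (i > 1L) 2L else 0L      # acceptor flank present
      dl <- if (i < n) 2L else 0L       # donor flank present
      key <- sprintf("%s:%d-%d", m$chrom, m$exons[i, "start"] - al,
                     m$exons[i, "end"] + dl)
      map[[key]] <- c(mi, i, al, dl)
    }
  }
  out <- new.env(hash = TRUE, parent = emptyenv())
  chroms <- sub("^[^.]*\\.", "", blocks$ref_src)
  for (b in seq_len(nrow(blocks))) {
    key <- sprintf("%s:%d-%d", chroms[b], blocks$ref_start[b],
                   blocks$ref_start[b] + blocks$ref_size[b])
    hit <- get0(key, envir = map)
    if (is.null(hit))
      stopf("MAF block %d (%s) does not match any model exon span", b, key)
    m <- models[[hit[1L]]]; i <- hit[2L]; al <- hit[3L]; dl <- hit[4L]
    rt <- tolower(blocks$ref_text[b]); qt <- tolower(blocks$q_text[b])
    nc <- nchar(rt)
    if (al > 0L && grepl("-", substr(rt, 1L, al), fixed = TRUE))
      stopf("gapped acceptor flank in MAF block %d", b)
    if (dl > 0L && grepl("-", substr(rt, nc - dl + 1L, nc), fixed = TRUE))
      stopf("gapped donor flank in MAF block %d", b)
    rec <- exon_alignment(
      m$gene_id, m$transcript_id, i - 1L, species, "ALIGNED",
      ref_aln = substr(rt, al + 1L, nc - dl),
      query_aln = substr(qt, al + 1L, nc - dl),
      query_acceptor = if (al > 0L) substr(qt, 1L, 2L) else NA_character_,
      query_donor = if (dl > 0L) substr(qt, nc - 1L, nc) else NA_character_,
      ref_acceptor = if (al > 0L) substr(rt, 1L, 2L) else NA_character_,
      ref_donor = if (dl > 0L) substr(rt, nc - 1L, nc) else NA_character_)
    ung <- gsub("-", "", rec$ref_aln, fixed = TRUE)
    if (nchar(ung) != m$exons[i, "end"] - m$exons[i, "start"])
      stopf("ungapped reference row of block %d does not match exon length", b)
    assign(sprintf("%s:%d", m$transcript_id, i - 1L), rec, envir = out)
  }
  res <- as.list(out)
  res[order(names(res))]
}

#' Read a query-context table
#'
#' Query syntenic sequence for exons that are absent from the alignment,
#' used to distinguish real deletions from assembly gaps. Columns:
#' `transcript_id`, `exon_index` (0-based), `context` (sequence, or `.`
#' when the syntenic interval is unresolvable).
#'
#' @param path TSV file.
#' @return named character vector `transcript_id:exon_index` -> context
#'   (NA for unresolvable).
#' @export
read_contexts <- function(path) {
  df <- read_gene_table(path)
  need <- c("transcript_id", "exon_index", "context")
  if (!all(need %in% names(df)))
    stopf("context table %s must have columns %s", path,
          paste(need, collapse = ", "))
  ctx <- as.character(df$context)
  ctx[ctx == "."] <- NA_character_
  stats::setNames(tolower(ctx),
                  sprintf("%s:%d", df$transcript_id, df$exon_index))
}
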