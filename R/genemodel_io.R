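# Gene models, sequences, trees and ontologies: the ingestion layer.
#
# Coordinate conventions used by every downstream module:
#   * genomic intervals are 0-based half-open (BED convention); GTF input is
#     converted on read;
#   * exons of a model are stored in TRANSCRIPTION order (for minus-strand
#     genes that is descending genomic order); all downstream analysis works
#     in transcription orientation and reverse-complementing happens at
#     ingestion only.

#' Construct a gene model
#'
#' A reference protein-coding transcript: its ordered coding exons, strand
#' and per-exon phases. Exons are given in transcription order as 0-based
#' half-open genomic intervals covering the coding portion only.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome / contig name.
#' @param strand "+" or "-".
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open), rows in transcription order.
#' @param is_principal whether this is a principal isoform of its gene.
#' @return an object of class `gene_model` with fields `phase_per_exon`
#'   (phase of exon i = cumulative coding length of earlier exons mod 3) and
#'   `cds_length`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       is_principal = TRUE) {
  stopifnot(is_string(gene_id), is_string(transcript_id), is_string(chrom))
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stopf("model %s has no coding exons", transcript_id)
  len <- exons[, "end"] - exons[, "start"]
  if (any(len <= 0L)) stopf("model %s has empty exons", transcript_id)
  gstart <- exons[, "start"]
  ord <- if (strand == "+") order(gstart) else order(-gstart)
  if (!identical(ord, seq_len(nrow(exons))))
    stopf("model %s: exons not in transcription order", transcript_id)
  # non-overlap in genomic space
  g <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(g) > 1L && any(g[-nrow(g), "end"] > g[-1L, "start"]))
    stopf("model %s: overlapping exons", transcript_id)
  cds_length <- sum(len)
  if (cds_length %% 3L != 0L)
    stopf("model %s: CDS length %d not divisible by 3",
          transcript_id, cds_length)
  phases <- as.integer(cumsum(c(0L, len[-length(len)])) %% 3L)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 phase_per_exon = phases, cds_length = cds_length,
                 is_principal = isTRUE(is_principal)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s  %s%s  %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand,
              nrow(x$exons), x$cds_length,
              if (x$is_principal) " [principal]" else ""))
  invisible(x)
}

# number of codons in the CDS
n_codons <- function(model) model$cds_length %/% 3L

# cumulative coding offsets (bp before exon i), length n_exons + 1
exon_offsets <- function(model) {
  len <- model$exons[, "end"] - model$exons[, "start"]
  cumsum(c(0L, len))
}

# 1-based codon span (start, end) of exon i (1-based exon number)
exon_codon_span <- function(model, i) {
  off <- exon_offsets(model)
  c(off[i] %/% 3L + 1L, (off[i + 1L] + 2L) %/% 3L)
}

#' Read gene models from BED12 or GTF
#'
#' BED12: the coding exons are the intersections of the blocks with the
#' `thickStart`/`thickEnd` interval. The `name` field encodes
#' `gene|transcript` or `gene|transcript|principal_flag` (flag 0/1, default
#' 1). GTF: `CDS` features are grouped by `transcript_id`; a transcript is
#' flagged principal when any of its CDS lines carries an
#' `appris_principal` tag. Models whose total coding length is not
#' divisible by 3 are rejected with a warning and listed in the `skipped`
#' attribute of the result.
#'
#' @param path input file.
#' @param format "auto" (by extension), "bed" or "gtf".
#' @return list of [gene_model()] objects; attribute `skipped` is a
#'   data.frame describing rejected records.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "bed") read_gene_models_bed(path) else read_gene_models_gtf(path)
}

read_gene_models_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  models <- list()
  skipped <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stopf("malformed BED12 record at line %d of %s (%d fields)",
            k, path, length(f))
    chrom <- f[1L]
    chromStart <- as.integer(f[2L])
    strand <- f[6L]
    thickStart <- as.integer(f[7L]); thickEnd <- as.integer(f[8L])
    nb <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    starts <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
    if (length(sizes) != nb || length(starts) != nb || anyNA(sizes) ||
        anyNA(starts))
      stopf("malformed BED12 blocks at line %d of %s", k, path)
    nm <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
    if (length(nm) < 2L)
      stopf("BED12 name at line %d must be gene|transcript[|principal]", k)
    principal <- if (length(nm) >= 3L) nm[3L] != "0" else TRUE
    bs <- chromStart + starts
    be <- bs + sizes
    cs <- pmax(bs, thickStart)
    ce <- pmin(be, thickEnd)
    keep <- ce > cs
    if (!any(keep)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = k, transcript_id = nm[2L], reason = "no CDS")
      next
    }
    ex <- cbind(start = cs[keep], end = ce[keep])
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    m <- tryCatch(gene_model(nm[1L], nm[2L], chrom, strand, ex, principal),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) {
      warnf("line %d of %s skipped: %s", k, path, m)
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = k, transcript_id = nm[2L], reason = m)
    } else models[[length(models) + 1L]] <- m
  }
  attr(models, "skipped") <- do.call(rbind, skipped)
  models
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1L))
}

read_gene_models_gtf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stopf("malformed GTF record at line %d of %s", bad[1L], path)
  feat <- vapply(fields, `[`, character(1L), 3L)
  cds <- fields[feat == "CDS"]
  if (!length(cds)) return(structure(list(), skipped = NULL))
  df <- data.frame(
    chrom = vapply(cds, `[`, character(1L), 1L),
    start = as.integer(vapply(cds, `[`, character(1L), 4L)) - 1L,
    end = as.integer(vapply(cds, `[`, character(1L), 5L)),
    strand = vapply(cds, `[`, character(1L), 7L),
    attrs = vapply(cds, `[`, character(1L), 9L),
    stringsAsFactors = FALSE)
  df$gene_id <- gtf_attr(df$attrs, "gene_id")
  df$transcript_id <- gtf_attr(df$attrs, "transcript_id")
  df$principal <- grepl("appris_principal", df$attrs, fixed = TRUE)
  if (anyNA(df$transcript_id) || anyNA(df$gene_id))
    stopf("GTF CDS records in %s lack gene_id/transcript_id attributes", path)
  models <- list(); skipped <- list()
  for (tid in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tid, , drop = FALSE]
    strand <- d$strand[1L]
    d <- d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    m <- tryCatch(
      gene_model(d$gene_id[1L], tid, d$chrom[1L], strand,
                 cbind(start = d$start, end = d$end), any(d$principal)),
      error = function(e) conditionMessage(e))
    if (is.character(m)) {
      warnf("transcript %s in %s skipped: %s", tid, path, m)
      skipped[[length(skipped) + 1L]] <-
        data.frame(line = NA_integer_, transcript_id = tid, reason = m)
    } else models[[length(models) + 1L]] <- m
  }
  attr(models, "skipped") <- do.call(rbind, skipped)
  models
}

#' Write gene models as BED12
#'
#' Inverse of [read_gene_models()] for the BED12 dialect (name field
#' `gene|transcript|principal_flag`; thick interval = coding span).
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_models_bed <- function(models, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(models, function(m) {
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    chromStart <- ex[1L, "start"]; chromEnd <- ex[nrow(ex), "end"]
    paste(m$chrom, chromStart, chromEnd,
          paste(m$gene_id, m$transcript_id,
                if (m$is_principal) "1" else "0", sep = "|"),
          0L, m$strand, chromStart, chromEnd, "0", nrow(ex),
          paste0(paste(ex[, "end"] - ex[, "start"], collapse = ","), ","),
          paste0(paste(ex[, "start"] - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}

#' Extract coding exon sequences in transcription orientation
#'
#' @param model a [gene_model()].
#' @param genome named character vector of chromosome sequences (or a file
#'   path to a FASTA, read via [read_fasta()]).
#' @return character vector of lower-case exon sequences, one per exon, in
#'   transcription order (minus-strand exons reverse-complemented).
#' @export
exon_sequences <- function(model, genome) {
  if (is_string(genome) && file.exists(genome)) genome <- read_fasta(genome)
  if (!model$chrom %in% names(genome))
    stopf("chromosome %s not in genome", model$chrom)
  chr <- genome[[model$chrom]]
  seqs <- apply(model$exons, 1L, function(e)
    substr(chr, e[1L] + 1L, e[2L]))
  seqs <- tolower(seqs)
  if (model$strand == "-") seqs <- revcomp(seqs)
  unname(seqs)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is what the string-based scanning code consumes.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(tolower(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @return `write_fasta`: invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(toupper(unlist(seqs))), path, width = 70L)
  invisible(path)
}

#' Read a species tree from Newick
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree; leaf labels must be unique.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse Newick file %s", path)
  if (anyDuplicated(tr$tip.label)) stopf("duplicate leaf labels in %s", path)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a phenotype ontology from OBO
#'
#' Minimal OBO reader covering `[Term]` stanzas with `id`, `name`, `is_a`
#' and `is_obsolete` lines, which is the subset needed for phenotype
#' propagation. The `is_a` graph must be acyclic and every term must reach
#' the single root. A term's level is 1 + the length of the SHORTEST `is_a`
#' path to the root (root = level 1, direct children of the root = level 2,
#' matching how MGI renders its phenotype hierarchy).
#'
#' @param path OBO file.
#' @return an object of class `ontology`: list with `terms` (data.frame
#'   `id`, `name`, `level`), `parents` (named list), `root`, and the igraph
#'   `graph` (edges child -> parent).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stopf("no [Term] stanzas in %s", path)
  bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  for (k in seq_along(term_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !grepl("^\\[", chunk)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"),
                                                 chunk, value = TRUE))
      if (length(v)) v else character(0)
    }
    if (length(get1("is_obsolete")) && get1("is_obsolete")[1L] == "true")
      next
    id <- get1("id")[1L]
    if (is.na(id) || !length(get1("id"))) next
    isa <- sub(" *!.*$", "", get1("is_a"))
    ids <- c(ids, id)
    nms <- c(nms, if (length(get1("name"))) get1("name")[1L] else id)
    parents[[id]] <- isa
  }
  make_ontology(ids, nms, parents)
}

# shared constructor for read_obo and the synthetic generator
make_ontology <- function(ids, names, parents) {
  if (anyDuplicated(ids)) stopf("duplicate term ids in ontology")
  parents <- parents[ids]
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown))
    stopf("is_a parent(s) not defined as terms: %s",
          paste(unknown, collapse = ", "))
  edges <- do.call(rbind, lapply(ids, function(id) {
    p <- parents[[id]]
    if (length(p)) cbind(id, p) else NULL
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(ids)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  if (!igraph::is_dag(g)) stopf("cycle in ontology is_a graph")
  roots <- ids[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stopf("ontology must have exactly one root (found %d)", length(roots))
  # level = 1 + shortest path length from term up to the root
  d <- igraph::distances(g, v = roots, mode = "in")[1L, ]
  if (any(!is.finite(d)))
    stopf("term(s) do not reach the root: %s",
          paste(ids[!is.finite(d[ids])], collapse = ", "))
  terms <- data.frame(id = ids, name = names,
                      level = as.integer(d[ids] + 1L),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, parents = parents, root = roots,
                 graph = g, .anc_cache = new.env(parent = emptyenv())),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, root %s, max level %d\n",
              nrow(x$terms), x$root, max(x$terms$level)))
  invisible(x)
}

#' Write an ontology as OBO
#'
#' @param ont an `ontology` object.
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    p <- ont$parents[[id]]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ont$terms$name[i]),
             if (length(p)) paste0("is_a: ", p), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Ancestors of ontology terms
#'
#' All terms reachable from `term` by following `is_a` edges upward,
#' excluding `term` itself (memoized).
#'
#' @param ont an `ontology`.
#' @param term a term id.
#' @return character vector of ancestor ids (includes the root).
#' @export
term_ancestors <- function(ont, term) {
  cache <- ont$.anc_cache
  if (!is.null(cache[[term]])) return(cache[[term]])
  res <- setdiff(
    names(igraph::subcomponent(ont$graph, term, mode = "out")), term)
  cache[[term]] <- res
  res
}

term_levels <- function(ont) {
  stats::setNames(ont$terms$level, ont$terms$id)
}
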