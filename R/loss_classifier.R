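# Per-gene loss classification from mutation lists.
#
# A gene is classified as lost in a query species if less than 60% of the
# reading frame remains intact AND at least 20% of its exons carry
# inactivating mutations; single-exon genes simply require at least two
# inactivating mutations. Both comparisons are taken literally: strictly
# below 60%, at least (>=) 20%, at least (>=) 2. A gene with several
# principal isoforms is lost only if EVERY principal isoform is lost (one
# intact isoform preserves gene function). Exons lying in assembly gaps
# (MISSING) contribute neither mutations nor to the exon denominator.

# codon span (start, end) affected by each mutation, on the 1-based codon
# axis of the reference CDS
mutation_codon_spans <- function(model, mutations) {
  L <- n_codons(model)
  if (!nrow(mutations))
    return(data.frame(start = integer(0), end = integer(0)))
  start <- integer(nrow(mutations)); end <- integer(nrow(mutations))
  for (r in seq_len(nrow(mutations))) {
    kind <- mutations$kind[r]
    if (kind == "GENE_DELETED") {
      start[r] <- 1L; end[r] <- L
    } else if (kind == "EXON_DELETED") {
      sp <- exon_codon_span(model, mutations$exon_index[r] + 1L)
      start[r] <- sp[1L]; end[r] <- sp[2L]
    } else {
      start[r] <- mutations$codon_position[r]
      end[r] <- mutations$codon_position[r]
    }
  }
  data.frame(start = start, end = end)
}

#' Fraction of the reading frame left intact
#'
#' The maximum share of the CDS codon axis unaffected by inactivating
#' mutations, measured as the larger of the clean 5' and 3' terminal
#' segments: `max((f-1)/L, (L-l)/L)` where `L` is the total codon count and
#' `f`/`l` are the first/last affected codons (1-based). Exon deletions
#' contribute their exon's full codon span, splice-site events anchor at
#' the adjacent exon-boundary codon, whole-gene deletions span everything.
#' With no mutations the fraction is 1. Setting `rule = "max_stretch"`
#' instead returns the largest clean stretch between ANY two consecutive
#' mutations (including the terminal segments), as an alternative reading
#' of "maximum percentage of the reading frame intact".
#'
#' @param model a [gene_model()].
#' @param mutations mutation data.frame for this transcript.
#' @param rule `"terminal_flank"` (default) or `"max_stretch"`.
#' @return a number in \[0, 1\].
#' @export
intact_fraction <- function(model, mutations,
                            rule = c("terminal_flank", "max_stretch")) {
  rule <- match.arg(rule)
  L <- n_codons(model)
  if (!nrow(mutations)) return(1)
  sp <- mutation_codon_spans(model, mutations)
  if (rule == "terminal_flank") {
    f <- min(sp$start); l <- max(sp$end)
    return(max((f - 1) / L, (L - l) / L))
  }
  # largest clean stretch between consecutive affected codons
  covered <- logical(L)
  for (i in seq_len(nrow(sp)))
    covered[sp$start[i]:sp$end[i]] <- TRUE
  r <- rle(covered)
  clean <- r$lengths[!r$values]
  if (!length(clean)) 0 else max(clean) / L
}

#' Classify one transcript
#'
#' Applies the loss rule to a single isoform.
#'
#' @param model a [gene_model()].
#' @param mutations mutation data.frame for this transcript (one species).
#' @param status per-exon status vector (`ALIGNED`/`DELETED`/`MISSING`).
#' @param thresholds a [loss_thresholds()].
#' @param rule intact-fraction rule, see [intact_fraction()].
#' @return list with `lost`, `no_data`, `intact_fraction`,
#'   `exon_fraction_hit`, `n_mutations`, `rationale`.
#' @export
classify_transcript <- function(model, mutations, status,
                                thresholds = loss_thresholds(),
                                rule = "terminal_flank") {
  n <- nrow(model$exons)
  if (all(status == "MISSING"))
    return(list(lost = NA, no_data = TRUE, intact_fraction = NA_real_,
                exon_fraction_hit = NA_real_, n_mutations = 0L,
                rationale = "NO_DATA"))
  n_eff <- sum(status != "MISSING")
  ifrac <- intact_fraction(model, mutations, rule)
  hit_exons <- unique(mutations$exon_index[!is.na(mutations$exon_index)])
  if (any(mutations$kind == "GENE_DELETED")) hit_exons <- seq_len(n) - 1L
  efrac <- length(hit_exons) / n_eff
  nmut <- nrow(mutations)
  if (any(mutations$kind == "GENE_DELETED")) {
    lost <- TRUE; rationale <- "GENE_DELETED"; ifrac <- 0
  } else if (n == 1L) {
    lost <- nmut >= thresholds$min_mutations_single_exon
    rationale <- if (lost) "SINGLE_EXON_MULTI_MUTATION" else "NOT_LOST"
  } else {
    lost <- ifrac < thresholds$max_intact_fraction &&
      efrac >= thresholds$min_exon_fraction_hit
    rationale <- if (lost) "FRAME_AND_EXON_RULE" else "NOT_LOST"
  }
  list(lost = lost, no_data = FALSE, intact_fraction = ifrac,
       exon_fraction_hit = efrac, n_mutations = nmut, rationale = rationale)
}

#' Classify one gene across its principal isoforms
#'
#' The gene is lost only if every principal isoform with data is lost.
#' `best_intact_fraction` is the maximum intact fraction over isoforms and
#' `exon_fraction_hit` comes from the isoform attaining that maximum. If
#' all isoforms are missing everywhere the verdict is `NO_DATA`.
#'
#' @param isoforms list of per-isoform results from
#'   [classify_transcript()].
#' @param gene_id,species identifiers for the output row.
#' @return one-row data.frame (a loss call).
#' @export
classify_gene <- function(isoforms, gene_id = "gene", species = "query") {
  with_data <- Filter(function(x) !x$no_data, isoforms)
  if (!length(with_data))
    return(data.frame(gene_id = gene_id, species = species, lost = NA,
                      best_intact_fraction = NA_real_,
                      exon_fraction_hit = NA_real_, n_mutations = 0L,
                      rationale = "NO_DATA", stringsAsFactors = FALSE))
  ifracs <- vapply(with_data, `[[`, numeric(1L), "intact_fraction")
  best <- which.max(ifracs)
  lost <- all(vapply(with_data, `[[`, logical(1L), "lost"))
  rationale <- if (lost) with_data[[best]]$rationale else "NOT_LOST"
  data.frame(gene_id = gene_id, species = species, lost = lost,
             best_intact_fraction = ifracs[best],
             exon_fraction_hit = with_data[[best]]$exon_fraction_hit,
             n_mutations = sum(vapply(with_data, `[[`, integer(1L),
                                      "n_mutations")),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Classify all genes of one species
#'
#' @param models list of [gene_model()] (principal isoforms only are used).
#' @param scan result of [scan_species()].
#' @param species species name.
#' @param thresholds a [loss_thresholds()].
#' @param rule intact-fraction rule, see [intact_fraction()].
#' @return data.frame of loss calls, one row per gene.
#' @export
classify_species <- function(models, scan, species = "query",
                             thresholds = loss_thresholds(),
                             rule = "terminal_flank") {
  models <- Filter(function(m) m$is_principal, models)
  by_gene <- split(models, vapply(models, `[[`, character(1L), "gene_id"))
  mut <- scan$mutations[scan$mutations$species == species, , drop = FALSE]
  mut_by_tx <- split(mut, mut$transcript_id)
  calls <- lapply(names(by_gene), function(g) {
    isoforms <- lapply(by_gene[[g]], function(m) {
      mm <- mut_by_tx[[m$transcript_id]]
      if (is.null(mm)) mm <- mut[0L, , drop = FALSE]
      classify_transcript(m, mm, scan$statuses[[m$transcript_id]],
                          thresholds, rule)
    })
    classify_gene(isoforms, g, species)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the gene-by-species loss matrix
#'
#' @param calls data.frame of loss calls (rows from [classify_gene()],
#'   possibly several species).
#' @return character matrix genes x species with entries `"LOST"`,
#'   `"INTACT"` or `NA` (no data); rows and columns sorted.
#' @export
build_loss_matrix <- function(calls) {
  genes <- sort(unique(calls$gene_id))
  species <- sort(unique(calls$species))
  m <- matrix(NA_character_, length(genes), length(species),
              dimnames = list(genes, species))
  idx <- cbind(match(calls$gene_id, genes), match(calls$species, species))
  m[idx] <- ifelse(is.na(calls$lost), NA_character_,
                   ifelse(calls$lost, "LOST", "INTACT"))
  m
}

#' Write / read a loss matrix TSV
#'
#' @param mat matrix from [build_loss_matrix()].
#' @param path file path.
#' @export
write_loss_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_gene_table(df, path)
}

#' @rdname write_loss_matrix
#' @export
read_loss_matrix <- function(path) {
  df <- read_gene_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
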