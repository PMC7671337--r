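# Ledgered synthetic data with the statistical structure the analysis
# assumes: a species tree with branch-specific, Dollo-consistent (and
# optionally convergent) loss events; reference gene models whose query
# alignments carry injected stop/frameshift/splice/exon-deletion mutations
# plus neutral synonymous substitutions, in-frame indels and assembly-gap
# scenarios; a phenotype ontology with per-gene annotation counts drawn
# from group-specific distributions; gene-class labels with configurable
# class-by-loss odds ratios; and read sets over mutation loci. Every draw
# is governed by a single mandatory seed, and a truth ledger records the
# expected output of every downstream stage.

# sample from a vector, immune to the scalar-x trap of sample()
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# row accumulator: collects named lists cheaply, materialized once
new_rows <- function() {
  e <- new.env(parent = emptyenv()); e$rows <- vector("list", 64L)
  e$n <- 0L; e
}
add_row <- function(acc, row) {
  acc$n <- acc$n + 1L
  if (acc$n > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
  acc$rows[[acc$n]] <- row
  invisible()
}
rows_to_df <- function(acc) {
  if (acc$n == 0L) return(NULL)
  rows <- acc$rows[seq_len(acc$n)]
  nms <- names(rows[[1L]])
  out <- lapply(nms, function(nm)
    unlist(lapply(rows, `[[`, nm), use.names = FALSE))
  names(out) <- nms
  as.data.frame(out, stringsAsFactors = FALSE)
}

rand_dna <- function(n) {
  paste(resample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
}

# synonymous codon table built from the standard genetic code
syn_env <- new.env(parent = emptyenv())
synonymous_codons <- function() {
  if (is.null(syn_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- tolower(names(gc))
    aas <- unname(gc)
    syn_env$tab <- lapply(seq_along(codons), function(i) {
      if (aas[i] == "*") return(character(0))
      setdiff(codons[aas == aas[i]], codons[i])
    })
    names(syn_env$tab) <- codons
  }
  syn_env$tab
}

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design of the real screen at desk scale: an
#' 8-species tree whose per-branch loss probability and convergence rate
#' are calibrated so that roughly a fifth of genes are lost somewhere and
#' roughly half of the lost genes are lost in more than one independent
#' lineage; gene models of 1-20 coding exons and 300-3000 bp of CDS; a
#' mutation mix dominated by stop codons and frameshifts; and phenotype /
#' gene-class distributions in which lost genes have fewer knockout
#' phenotypes and are depleted in disease, essential and lethal genes but
#' enriched in dispensable genes.
#'
#' @param seed mandatory integer seed governing every draw.
#' @param n_genes,n_species cohort dimensions.
#' @param tree optional `ape::phylo` to use instead of a random tree.
#' @param branch_loss_prob per-branch probability of a first loss event.
#' @param convergence_rate per-branch probability of an additional,
#'   independent loss event once the gene is already lost somewhere.
#' @param mutation_mix named relative rates for `PREMATURE_STOP`,
#'   `FRAMESHIFT`, `SPLICE`, `EXON_DELETED`, `GENE_DELETED`.
#' @param syn_sub_rate per-codon probability of a neutral synonymous
#'   substitution in aligned exons.
#' @param inframe_del_rate per-exon probability of a neutral in-frame
#'   (3 bp) deletion.
#' @param assembly_gap_rate per-exon probability that an exon falls in an
#'   assembly gap (missing data).
#' @param na_rate per-gene-per-species probability that the whole locus is
#'   unresolvable (missing genome region).
#' @param n_exons_range,cds_codons_range gene-model geometry.
#' @param pleiotropy_lambda named Poisson means (`retained`, `lost`) of the
#'   per-gene phenotype-annotation count.
#' @param annotation_coverage fraction of genes with knockout data.
#' @param digenic_rate probability that a gene additionally carries a
#'   digenic (arity-2) annotation row, which downstream filtering removes.
#' @param class_base_rate named base membership rates among retained genes
#'   for `DISEASE`, `ESSENTIAL`, `LETHAL`, `DISPENSABLE` (a rate of 0
#'   disables the class).
#' @param class_odds_ratio named class-by-loss odds ratios (odds of class
#'   membership for lost genes relative to retained genes).
#' @param read_coverage reads generated over each validated mutation locus.
#' @param read_length,read_error_rate read geometry and per-base error.
#' @param ancestral_read_fraction fraction of reads drawn from the
#'   ancestral haplotype.
#' @param max_read_loci number of mutation loci for which read sets are
#'   emitted.
#' @param min_gap_run N-run length written into assembly-gap contexts.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 200L,
                       n_species = 8L,
                       tree = NULL,
                       branch_loss_prob = 0.018,
                       convergence_rate = 0.25,
                       mutation_mix = c(PREMATURE_STOP = 0.35,
                                        FRAMESHIFT = 0.35, SPLICE = 0.15,
                                        EXON_DELETED = 0.13,
                                        GENE_DELETED = 0.02),
                       syn_sub_rate = 0.02,
                       inframe_del_rate = 0.01,
                       assembly_gap_rate = 0.02,
                       na_rate = 0.02,
                       n_exons_range = c(1L, 20L),
                       cds_codons_range = c(100L, 1000L),
                       pleiotropy_lambda = c(retained = 6, lost = 4),
                       annotation_coverage = 0.85,
                       digenic_rate = 0.1,
                       class_base_rate = c(DISEASE = 0.15, ESSENTIAL = 0.09,
                                           LETHAL = 0.15,
                                           DISPENSABLE = 0.10),
                       class_odds_ratio = c(DISEASE = 0.4, ESSENTIAL = 0.25,
                                            LETHAL = 0.3, DISPENSABLE = 2.0),
                       read_coverage = 10L,
                       read_length = 60L,
                       read_error_rate = 0,
                       ancestral_read_fraction = 0,
                       max_read_loci = 50L,
                       min_gap_run = 10L) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(branch_loss_prob, convergence_rate, syn_sub_rate,
             inframe_del_rate, assembly_gap_rate, na_rate,
             annotation_coverage, digenic_rate, read_error_rate,
             ancestral_read_fraction, class_base_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(mutation_mix < 0) || sum(mutation_mix) <= 0)
    stopf("mutation_mix must be non-negative with positive sum")
  if (any(pleiotropy_lambda < 0) || any(class_odds_ratio < 0))
    stopf("rates must be non-negative")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# ---------------------------------------------------------------------------
# reference genome and gene models

build_reference <- function(config) {
  syn <- synonymous_codons()
  all_codons <- names(syn)
  internal <- setdiff(all_codons, STOP_CODONS)
  pieces <- vector("list", 4L * config$n_genes); np <- 0L
  push <- function(s) { np <<- np + 1L
    if (np > length(pieces)) length(pieces) <<- 2L * length(pieces)
    pieces[[np]] <<- s }
  pos <- 0L
  models <- vector("list", config$n_genes)
  exon_seqs <- vector("list", config$n_genes)
  spacer <- 80L; intron_inner <- 20L
  for (g in seq_len(config$n_genes)) {
    L <- resample(seq(config$cds_codons_range[1L],
                      config$cds_codons_range[2L]), 1L)
    cds_len <- 3L * L
    max_ex <- max(1L, min(config$n_exons_range[2L], cds_len %/% 60L))
    n_ex <- resample(seq(config$n_exons_range[1L], max_ex), 1L)
    extra <- if (n_ex > 0L)
      as.vector(stats::rmultinom(1L, cds_len - 60L * n_ex,
                                 rep(1 / n_ex, n_ex)))
    lens <- 60L + extra
    cds <- c("atg", resample(internal, L - 2L, replace = TRUE),
             resample(STOP_CODONS, 1L))
    cds <- paste(cds, collapse = "")
    offs <- cumsum(c(0L, lens))
    seqs <- substring(cds, offs[-length(offs)] + 1L, offs[-1L])
    gid <- sprintf("G%04d", g); tid <- sprintf("G%04d.T1", g)
    sp <- rand_dna(spacer)
    push(sp); pos <- pos + spacer
    exons <- matrix(0L, n_ex, 2L, dimnames = list(NULL, c("start", "end")))
    for (i in seq_len(n_ex)) {
      exons[i, ] <- c(pos, pos + lens[i])
      push(seqs[i]); pos <- pos + lens[i]
      if (i < n_ex) {
        intr <- paste0("gt", rand_dna(intron_inner), "ag")
        push(intr); pos <- pos + nchar(intr)
      }
    }
    models[[g]] <- gene_model(gid, tid, "chr1", "+", exons, TRUE)
    exon_seqs[[g]] <- seqs
  }
  push(rand_dna(spacer))
  list(models = models, exon_seqs = exon_seqs,
       genome = c(chr1 = paste(unlist(pieces[seq_len(np)]),
                               collapse = "")))
}

# ---------------------------------------------------------------------------
# loss histories

#' Simulate Dollo-consistent loss histories
#'
#' Branches are visited in preorder; a gene acquires its first loss event
#' on an eligible branch with probability `branch_loss_prob`, and further
#' events on branches not descending from an existing event with
#' probability `convergence_rate`. Once lost on a branch, all descendant
#' leaves are lost (no regain).
#'
#' @param config a [sim_config()].
#' @param tree an `ape::phylo`; defaults to a random tree of
#'   `config$n_species` leaves (the caller is responsible for seeding).
#' @return list with `tree`, `truth` (gene x species matrix of
#'   `"LOST"`/`"INTACT"`), `na_mask` (logical matrix of unresolvable
#'   loci), `n_lineages` (canonical independent-lineage count per gene),
#'   `event_branches` (per-gene character vector of branch labels).
#' @export
simulate_loss_history <- function(config, tree = NULL) {
  tree <- tree %||% config$tree %||%
    ape::rtree(config$n_species,
               tip.label = sprintf("sp%02d", seq_len(config$n_species)))
  n <- ape::Ntip(tree)
  ng <- config$n_genes
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  ntot <- n + tree$Nnode
  blocked <- matrix(FALSE, ng, ntot)
  has_event <- rep(FALSE, ng)
  events <- matrix(FALSE, ng, nrow(edge))
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    pr <- ifelse(has_event, config$convergence_rate,
                 config$branch_loss_prob)
    ev <- !blocked[, p] & stats::runif(ng) < pr
    events[, k] <- ev
    blocked[, ch] <- blocked[, p] | ev
    has_event <- has_event | ev
  }
  truth <- matrix(ifelse(blocked[, seq_len(n)], "LOST", "INTACT"),
                  ng, n, dimnames = list(sprintf("G%04d", seq_len(ng)),
                                         tree$tip.label))
  na_mask <- matrix(stats::runif(ng * n) < config$na_rate, ng, n,
                    dimnames = dimnames(truth))
  canon <- canonical_lineages(tree, truth)
  list(tree = tree, truth = truth, na_mask = na_mask,
       n_lineages = canon$n, event_branches = canon$branches)
}

# canonical (Dollo) lineage counts from truth leaf states: maximal all-lost
# subtrees, computed by direct recursion (independent of the inference
# code path used by the pipeline)
canonical_lineages <- function(tree, truth) {
  n <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  labs <- node_labels_or_default(tree)
  leaves_below <- vector("list", n + tree$Nnode)
  all_lost_count <- function(node, lost_vec) {
    # returns c(all_lost flag, events below when not grouped)
    NULL
  }
  ng <- nrow(truth)
  n_out <- integer(ng); br_out <- vector("list", ng)
  # precompute leaf sets per node
  get_leaves <- function(node) {
    if (!is.null(leaves_below[[node]])) return(leaves_below[[node]])
    res <- if (node <= n) node else
      unlist(lapply(kids[[as.character(node)]], get_leaves))
    leaves_below[[node]] <<- res
    res
  }
  for (v in seq_len(n + tree$Nnode)) get_leaves(v)
  for (g in seq_len(ng)) {
    lost <- truth[g, ] == "LOST"
    ev <- integer(0)
    walk <- function(node) {
      lv <- leaves_below[[node]]
      if (all(lost[lv])) { ev <<- c(ev, node); return(invisible()) }
      if (node > n)
        for (ch in kids[[as.character(node)]])
          if (any(lost[leaves_below[[ch]]])) walk(ch)
      invisible()
    }
    if (any(lost)) walk(n + 1L)
    n_out[g] <- length(ev)
    br_out[[g]] <- labs[ev]
  }
  list(n = n_out, branches = br_out)
}

# ---------------------------------------------------------------------------
# alignment emission with mutation injection

# fully-contained codon range of exon e (1-based codons), clamped away
# from the first and terminal codon
eligible_codons <- function(off, e, L) {
  c_lo <- (off[e] + 2L) %/% 3L + 1L
  c_hi <- off[e + 1L] %/% 3L
  lo <- max(c_lo, 2L); hi <- min(c_hi, L - 1L)
  if (lo > hi) integer(0) else lo:hi
}

# plan the injected mutations for one lost gene x species
plan_loss_mutations <- function(config, model, non_missing) {
  L <- n_codons(model)
  n_ex <- nrow(model$exons)
  off <- exon_offsets(model)
  mix <- config$mutation_mix
  mix <- mix[setdiff(names(mix), "GENE_DELETED")]
  mix <- mix / sum(mix)
  window <- seq(floor(0.4 * L) + 2L, floor(0.6 * L))
  anchored <- integer(0)
  for (e in non_missing) {
    if (length(intersect(eligible_codons(off, e, L), window))) {
      anchored <- c(anchored, e)
    }
  }
  if (!length(anchored))
    stopf("no anchor exon available (gene %s)", model$gene_id)
  e_mid <- anchored[1L]
  if (n_ex == 1L) {
    cods <- eligible_codons(off, 1L, L)
    c0 <- resample(intersect(cods, window), 1L)
    c1 <- resample(setdiff(cods, (c0 - 2L):(c0 + 2L)), 1L)
    kinds <- resample(c("PREMATURE_STOP", "FRAMESHIFT"), 2L, replace = TRUE)
    return(data.frame(exon = c(1L, 1L), kind = kinds, codon = c(c0, c1),
                      stringsAsFactors = FALSE))
  }
  k <- max(1L, ceiling(0.2 * length(non_missing)))
  others <- setdiff(non_missing, e_mid)
  exons <- c(e_mid, resample(others, min(k - 1L, length(others))))
  kinds <- resample(names(mix), length(exons), replace = TRUE)
  # anchor exon must carry a mutation covering the mid window
  if (kinds[1L] == "SPLICE") kinds[1L] <- "PREMATURE_STOP"
  codons <- integer(length(exons))
  for (i in seq_along(exons)) {
    e <- exons[i]
    cods <- eligible_codons(off, e, L)
    codons[i] <- switch(
      kinds[i],
      PREMATURE_STOP = ,
      FRAMESHIFT = if (i == 1L) resample(intersect(cods, window), 1L)
      else if (length(cods)) resample(cods, 1L) else NA_integer_,
      SPLICE = NA_integer_,
      EXON_DELETED = NA_integer_)
    if (kinds[i] %in% c("PREMATURE_STOP", "FRAMESHIFT") &&
        is.na(codons[i]))
      kinds[i] <- "EXON_DELETED"
  }
  data.frame(exon = exons, kind = kinds, codon = codons,
             stringsAsFactors = FALSE)
}

# build the aligned exon pair for one exon given injected + neutral edits.
# Edits are expressed in within-exon reference coordinates (1-based).
build_exon_alignment <- function(ref_seq, subs, dels, ins) {
  rc <- chars(ref_seq)
  qc <- rc
  for (s in subs) qc[s$pos:(s$pos + nchar(s$repl) - 1L)] <- chars(s$repl)
  for (d in dels) qc[d$pos:(d$pos + d$len - 1L)] <- "-"
  if (length(ins)) {
    for (i in ins[order(-vapply(ins, `[[`, integer(1L), "after"))]) {
      at <- i$after
      rc <- append(rc, rep("-", nchar(i$seq)), after = at)
      qc <- append(qc, chars(i$seq), after = at)
    }
  }
  list(ref = paste(rc, collapse = ""), query = paste(qc, collapse = ""),
       rc = rc, qc = qc)
}

# neutral edit positions for one exon: synonymous substitutions and
# optional in-frame deletion, avoiding +-2 codons around blocked codons
neutral_edits <- function(config, off, e, L, ref_seq, blocked_codons) {
  cods <- eligible_codons(off, e, L)
  avoid <- unique(unlist(lapply(blocked_codons,
                                function(c0) (c0 - 2L):(c0 + 2L))))
  cods <- setdiff(cods, avoid)
  subs <- list(); dels <- list()
  if (length(cods)) {
    hit <- cods[stats::runif(length(cods)) < config$syn_sub_rate]
    syn <- synonymous_codons()
    for (c0 in hit) {
      p <- 3L * (c0 - 1L) - off[e] + 1L
      cod <- substr(ref_seq, p, p + 2L)
      alts <- syn[[cod]]
      if (length(alts))
        subs[[length(subs) + 1L]] <- list(pos = p, repl = resample(alts, 1L))
    }
    cods <- setdiff(cods, hit)
    if (length(cods) > 2L &&
        stats::runif(1L) < config$inframe_del_rate) {
      c0 <- resample(cods, 1L)
      dels[[length(dels) + 1L]] <-
        list(pos = 3L * (c0 - 1L) - off[e] + 1L, len = 3L)
    }
  }
  list(subs = subs, dels = dels)
}

bad_donors <- c("aa", "at", "ac", "ag", "ca", "cc", "ta", "tt")
bad_acceptors <- c("aa", "ac", "at", "ca", "cc", "gg", "tg", "tt")

# emit alignments, contexts, ledger mutations and expected calls for one
# species; read_state accumulates validation loci as they are chosen
build_species_data <- function(config, ref, hist, sp, thresholds,
                               read_state) {
  genome <- ref$genome[["chr1"]]
  srcsize <- nchar(genome)
  blocks <- new_rows(); ctx_rows <- new_rows(); mut_rows <- new_rows()
  call_rows <- new_rows()
  gap_ctx <- function() paste0(rand_dna(20L),
                               strrep("n", max(config$min_gap_run, 12L)),
                               rand_dna(20L))
  for (g in seq_len(config$n_genes)) {
    model <- ref$models[[g]]
    seqs <- ref$exon_seqs[[g]]
    n_ex <- nrow(model$exons)
    off <- exon_offsets(model)
    L <- n_codons(model)
    gid <- model$gene_id; tid <- model$transcript_id
    truth_lost <- hist$truth[g, sp] == "LOST"
    if (hist$na_mask[g, sp]) {
      for (i in seq_len(n_ex))
        add_row(ctx_rows, list(gene_id = gid, transcript_id = tid,
                               exon_index = i - 1L, context = "."))
      add_row(call_rows, list(
        gene_id = gid, species = sp, truth_lost = truth_lost,
        observed = NA, expected_lost = NA, intact_fraction = NA_real_,
        exon_fraction_hit = NA_real_, n_mutations = 0L,
        rationale = "NO_DATA"))
      next
    }
    status <- rep("ALIGNED", n_ex)
    plan <- NULL
    if (truth_lost && stats::runif(1L) <
        config$mutation_mix[["GENE_DELETED"]] /
        sum(config$mutation_mix)) {
      status[] <- "DELETED"
      add_row(mut_rows, list(
        gene_id = gid, transcript_id = tid, species = sp,
        kind = "GENE_DELETED", exon_index = NA_integer_,
        codon_position = NA_integer_))
      add_row(call_rows, list(
        gene_id = gid, species = sp, truth_lost = TRUE, observed = TRUE,
        expected_lost = TRUE, intact_fraction = 0,
        exon_fraction_hit = 1, n_mutations = 1L,
        rationale = "GENE_DELETED"))
      for (i in seq_len(n_ex))
        add_row(ctx_rows, list(
          gene_id = gid, transcript_id = tid, exon_index = i - 1L,
          context = rand_dna(40L)))
      next
    }
    # assembly gaps; for lost genes keep the anchor window available by
    # never gapping every anchored exon (exon 1 kept aligned as fallback)
    if (config$assembly_gap_rate > 0) {
      gap <- stats::runif(n_ex) < config$assembly_gap_rate
      if (truth_lost) {
        window <- seq(floor(0.4 * L) + 2L, floor(0.6 * L))
        anch <- which(vapply(seq_len(n_ex), function(e)
          length(intersect(eligible_codons(off, e, L), window)) > 0L,
          logical(1L)))
        if (length(anch)) gap[anch[1L]] <- FALSE
      }
      if (all(gap)) gap[1L] <- FALSE
      status[gap] <- "MISSING"
    }
    non_missing <- which(status != "MISSING")
    if (truth_lost) {
      plan <- plan_loss_mutations(config, model, non_missing)
      status[plan$exon[plan$kind == "EXON_DELETED"]] <- "DELETED"
    }
    # per-exon edits and emission
    spans <- NULL
    if (!is.null(plan)) {
      spans <- matrix(0L, nrow(plan), 2L)
    }
    for (i in seq_len(n_ex)) {
      if (status[i] == "MISSING") {
        add_row(ctx_rows, list(
          gene_id = gid, transcript_id = tid, exon_index = i - 1L,
          context = gap_ctx()))
        next
      }
      if (status[i] == "DELETED") {
        add_row(ctx_rows, list(
          gene_id = gid, transcript_id = tid, exon_index = i - 1L,
          context = rand_dna(40L)))
        next
      }
      subs <- list(); dels <- list(); ins <- list()
      donor_q <- if (i < n_ex) "gt" else NA_character_
      accept_q <- if (i > 1L) "ag" else NA_character_
      blocked <- integer(0)
      inj <- if (!is.null(plan)) which(plan$exon == i &
                                         plan$kind != "EXON_DELETED")
      else integer(0)
      point_mut <- NULL
      for (j in inj) {
        kind <- plan$kind[j]; c0 <- plan$codon[j]
        if (kind == "PREMATURE_STOP") {
          p <- 3L * (c0 - 1L) - off[i] + 1L
          refc <- substr(seqs[i], p, p + 2L)
          newc <- resample(setdiff(STOP_CODONS, refc), 1L)
          subs[[length(subs) + 1L]] <- list(pos = p, repl = newc)
          blocked <- c(blocked, c0)
          spans[j, ] <- c(c0, c0)
          add_row(mut_rows, list(
            gene_id = gid, transcript_id = tid, species = sp,
            kind = "PREMATURE_STOP", exon_index = i - 1L,
            codon_position = c0))
          point_mut <- point_mut %||% list(kind = "PREMATURE_STOP",
                                           codon = c0, pos = p,
                                           ref = refc, query = newc)
        } else if (kind == "FRAMESHIFT") {
          p <- 3L * (c0 - 1L) - off[i] + 1L
          is_del <- stats::runif(1L) < 0.5
          max_len <- off[i + 1L] - 3L * (c0 - 1L)
          len <- resample(intersect(c(1L, 2L, 4L, 5L), seq_len(max_len)), 1L)
          if (is_del) {
            dels[[length(dels) + 1L]] <- list(pos = p, len = len)
            kindlab <- "FRAMESHIFT_DEL"
            point_mut <- point_mut %||% list(
              kind = kindlab, codon = c0, pos = p, len = len,
              ref = substr(seqs[i], p, p + len - 1L), query = "-")
          } else {
            insseq <- rand_dna(len)
            ins[[length(ins) + 1L]] <- list(after = p, seq = insseq)
            kindlab <- "FRAMESHIFT_INS"
            point_mut <- point_mut %||% list(kind = kindlab, codon = c0,
                                             pos = p, len = len,
                                             ref = "-", query = insseq)
          }
          blocked <- c(blocked, c0)
          spans[j, ] <- c(c0, c0)
          add_row(mut_rows, list(
            gene_id = gid, transcript_id = tid, species = sp,
            kind = kindlab, exon_index = i - 1L, codon_position = c0))
        } else if (kind == "SPLICE") {
          has_donor <- i < n_ex
          use_donor <- if (has_donor && i > 1L) stats::runif(1L) < 0.5
          else has_donor
          if (use_donor) {
            donor_q <- resample(bad_donors, 1L)
            cb <- (off[i + 1L] + 2L) %/% 3L
            add_row(mut_rows, list(
              gene_id = gid, transcript_id = tid, species = sp,
              kind = "SPLICE_DONOR", exon_index = i - 1L,
              codon_position = cb))
          } else {
            accept_q <- resample(bad_acceptors, 1L)
            cb <- off[i] %/% 3L + 1L
            add_row(mut_rows, list(
              gene_id = gid, transcript_id = tid, species = sp,
              kind = "SPLICE_ACCEPTOR", exon_index = i - 1L,
              codon_position = cb))
          }
          blocked <- c(blocked, cb)
          spans[j, ] <- c(cb, cb)
        }
      }
      ne <- neutral_edits(config, off, i, L, seqs[i], blocked)
      subs <- c(subs, ne$subs); dels <- c(dels, ne$dels)
      aln <- build_exon_alignment(seqs[i], subs, dels, ins)
      al <- if (i > 1L) 2L else 0L; dl <- if (i < n_ex) 2L else 0L
      ref_text <- paste0(if (al) "ag" else "", aln$ref,
                         if (dl) "gt" else "")
      q_text <- paste0(if (al) accept_q else "", aln$query,
                       if (dl) donor_q else "")
      rs <- model$exons[i, "start"] - al
      add_row(blocks, list(
        ref_src = "ref.chr1", ref_start = rs,
        ref_size = model$exons[i, "end"] + dl - rs, ref_strand = "+",
        ref_srcsize = srcsize, ref_text = ref_text,
        q_src = paste0(sp, ".chr1"), q_start = rs,
        q_size = sum(chars(q_text) != "-"), q_strand = "+",
        q_srcsize = srcsize, q_text = q_text))
      # validation locus for the first point mutation, quota permitting
      if (!is.null(point_mut) && read_state$quota > 0L)
        register_read_locus(config, read_state, model, genome, i,
                            aln, point_mut, sp)
    }
    # exon-deletion ledger rows and spans
    if (!is.null(plan)) {
      for (j in which(plan$kind == "EXON_DELETED")) {
        e <- plan$exon[j]
        sp_codons <- exon_codon_span(model, e)
        spans[j, ] <- sp_codons
        add_row(mut_rows, list(
          gene_id = gid, transcript_id = tid, species = sp,
          kind = "EXON_DELETED", exon_index = e - 1L,
          codon_position = NA_integer_))
      }
      f <- min(spans[, 1L]); l <- max(spans[, 2L])
      ifrac <- max((f - 1) / L, (L - l) / L)
      n_eff <- sum(status != "MISSING")
      efrac <- length(unique(plan$exon)) / n_eff
      rationale <- if (n_ex == 1L) "SINGLE_EXON_MULTI_MUTATION"
      else "FRAME_AND_EXON_RULE"
      add_row(call_rows, list(
        gene_id = gid, species = sp, truth_lost = TRUE, observed = TRUE,
        expected_lost = TRUE, intact_fraction = ifrac,
        exon_fraction_hit = efrac, n_mutations = nrow(plan),
        rationale = rationale))
    } else {
      all_missing <- all(status == "MISSING")
      add_row(call_rows, list(
        gene_id = gid, species = sp, truth_lost = FALSE,
        observed = if (all_missing) NA else FALSE,
        expected_lost = if (all_missing) NA else FALSE,
        intact_fraction = if (all_missing) NA_real_ else 1,
        exon_fraction_hit = if (all_missing) NA_real_ else 0,
        n_mutations = 0L,
        rationale = if (all_missing) "NO_DATA" else "NOT_LOST"))
    }
  }
  list(blocks = rows_to_df(blocks),
       contexts = rows_to_df(ctx_rows),
       mutations = rows_to_df(mut_rows),
       calls = rows_to_df(call_rows))
}

# choose a validation locus: build the query contig around the mutated
# exon, locate the variant on it, and synthesize reads
register_read_locus <- function(config, read_state, model, genome, i,
                                aln, pm, sp) {
  flank <- 60L
  estart <- model$exons[i, "start"]; eend <- model$exons[i, "end"]
  up <- substr(genome, max(1L, estart - flank + 1L), estart)
  down <- substr(genome, eend + 1L, min(nchar(genome), eend + flank))
  q_exon <- gsub("-", "", aln$query, fixed = TRUE)
  contig <- paste0(up, q_exon, down)
  # query position of a reference within-exon position
  ref_cols <- cumsum(aln$rc != "-")
  qpos_of <- function(refpos, after = FALSE) {
    base <- if (refpos == 0L) 0L else {
      col <- match(refpos, ref_cols)
      sum(aln$qc[seq_len(col)] != "-")
    }
    if (after) base + 1L else base
  }
  pos <- switch(pm$kind,
                PREMATURE_STOP = nchar(up) + qpos_of(pm$pos - 1L) + 1L,
                FRAMESHIFT_DEL = nchar(up) +
                  qpos_of(pm$pos + pm$len - 1L, after = TRUE),
                FRAMESHIFT_INS = nchar(up) + qpos_of(pm$pos) + 1L)
  locus_id <- sprintf("%s_%s_e%d", model$gene_id, sp, i - 1L)
  ref_allele <- if (pm$ref == "-") "-" else pm$ref
  query_allele <- if (pm$query == "-") "-" else pm$query
  ctx <- extract_context(contig, pos, ref_allele, query_allele,
                         flank_bp = 50L)
  rl <- config$read_length
  n_reads <- config$read_coverage
  n_anc <- round(n_reads * config$ancestral_read_fraction)
  make_reads <- function(context, var, n) {
    if (n <= 0L) return(character(0))
    len <- nchar(context)
    lo <- max(1L, var[2L] - rl + 1L)
    hi <- max(lo, min(var[1L], len - rl + 1L))
    starts <- resample(lo:hi, n, replace = TRUE)
    vapply(starts, function(s) {
      rd <- substr(context, s, min(len, s + rl - 1L))
      if (config$read_error_rate > 0) {
        rc <- chars(rd)
        err <- stats::runif(length(rc)) < config$read_error_rate
        if (any(err))
          rc[err] <- vapply(rc[err], function(b)
            resample(setdiff(c("a", "c", "g", "t"), b), 1L), character(1L))
        rd <- paste(rc, collapse = "")
      }
      if (stats::runif(1L) < 0.5) revcomp(rd) else rd
    }, character(1L))
  }
  reads <- c(make_reads(ctx$mutant, ctx$mutant_var, n_reads - n_anc),
             make_reads(ctx$ancestral, ctx$ancestral_var, n_anc))
  expected <- if (config$read_error_rate > 0) NA_character_
  else if (!length(reads)) "NO_DATA"
  else if (n_anc > 0L) "UNCONFIRMED"
  else if (n_reads - n_anc >= 5L) "CONFIRMED" else "UNCONFIRMED"
  read_state$loci[[length(read_state$loci) + 1L]] <- data.frame(
    locus_id = locus_id, gene_id = model$gene_id,
    transcript_id = model$transcript_id, species = sp, kind = pm$kind,
    codon_position = pm$codon, contig_id = locus_id, pos = pos,
    ref_allele = ref_allele, query_allele = query_allele,
    expected_status = expected, stringsAsFactors = FALSE)
  read_state$contigs[[locus_id]] <- contig
  read_state$reads[[locus_id]] <- reads
  read_state$quota <- read_state$quota - 1L
  invisible()
}

#' Emit alignments for all species
#'
#' @param config a [sim_config()].
#' @param ref reference bundle from the generator (models, exon sequences,
#'   genome).
#' @param hist result of [simulate_loss_history()].
#' @param dir output directory (`aln/<species>.maf`,
#'   `contexts/<species>.tsv`, read sets); `NULL` keeps everything in
#'   memory.
#' @return list with per-species `blocks`/`contexts`, the ledger
#'   `mutations` and `calls` tables, and the validation `loci` bundle.
#' @export
emit_alignments <- function(config, ref, hist, dir = NULL) {
  read_state <- new.env(parent = emptyenv())
  read_state$quota <- as.integer(config$max_read_loci)
  read_state$loci <- list(); read_state$contigs <- list()
  read_state$reads <- list()
  species <- colnames(hist$truth)
  muts <- list(); calls <- list(); per_species <- list()
  for (sp in species) {
    d <- build_species_data(config, ref, hist, sp, NULL, read_state)
    per_species[[sp]] <- d
    if (!is.null(d$mutations)) muts[[sp]] <- d$mutations
    calls[[sp]] <- d$calls
    if (!is.null(dir)) {
      write_maf(d$blocks, file.path(dir, "aln", paste0(sp, ".maf")))
      ctx <- d$contexts %||% data.frame(
        gene_id = character(0), transcript_id = character(0),
        exon_index = integer(0), context = character(0))
      write_gene_table(ctx, file.path(dir, "contexts", paste0(sp, ".tsv")))
    }
  }
  loci <- if (length(read_state$loci)) do.call(rbind, read_state$loci)
  else NULL
  if (!is.null(dir) && !is.null(loci)) {
    write_gene_table(loci, file.path(dir, "validation_loci.tsv"))
    write_fasta(unlist(read_state$contigs),
                file.path(dir, "reads", "contigs.fa"))
    for (id in names(read_state$reads)) {
      rds <- read_state$reads[[id]]
      fq <- file.path(dir, "reads", paste0(id, ".fastq"))
      dir.create(dirname(fq), showWarnings = FALSE, recursive = TRUE)
      if (length(rds))
        writeLines(paste0("@", id, "_r", seq_along(rds), "\n",
                          toupper(rds), "\n+\n",
                          strrep("I", nchar(rds))), fq)
      else writeLines(character(0), fq)
    }
  }
  list(per_species = per_species,
       mutations = if (length(muts)) do.call(rbind, c(muts,
                                                      make.row.names = FALSE))
       else NULL,
       calls = do.call(rbind, c(calls, make.row.names = FALSE)),
       loci = loci, contigs = read_state$contigs,
       reads = read_state$reads)
}

# ---------------------------------------------------------------------------
# ontology, annotations and gene classes

#' Build the synthetic phenotype ontology
#'
#' Five-level DAG: a root, level-2 systems (including "normal phenotype"),
#' level-3 phenotypes (including "no abnormal phenotype detected" under the
#' normal branch and "prenatal lethality"), level-4 phenotypes (the
#' annotation vocabulary; some carry two parents, a few also a level-2
#' parent so that the shortest-path level rule is exercised), and level-5
#' leaves.
#'
#' @param n_l2,n_l3,n_l4,n_l5 branch sizes.
#' @return an `ontology` plus attributes `annot_pool` (level-4 annotation
#'   vocabulary), `normal`, `no_abnormal`, `lethal` term ids.
#' @export
build_sim_ontology <- function(n_l2 = 10L, n_l3 = 25L, n_l4 = 80L,
                               n_l5 = 30L) {
  ids <- "MP:0000001"; nms <- "mammalian phenotype"
  parents <- list("MP:0000001" = character(0))
  l2 <- sprintf("MP:%07d", 1000L + seq_len(n_l2))
  for (k in seq_along(l2)) {
    ids <- c(ids, l2[k]); nms <- c(nms, sprintf("system %d phenotype", k))
    parents[[l2[k]]] <- "MP:0000001"
  }
  normal <- "MP:0002873"
  ids <- c(ids, normal); nms <- c(nms, "normal phenotype")
  parents[[normal]] <- "MP:0000001"
  no_abn <- "MP:0002169"
  ids <- c(ids, no_abn); nms <- c(nms, "no abnormal phenotype detected")
  parents[[no_abn]] <- normal
  lethal <- "MP:0002080"
  ids <- c(ids, lethal); nms <- c(nms, "prenatal lethality")
  parents[[lethal]] <- l2[1L]
  l3 <- sprintf("MP:%07d", 3000L + seq_len(n_l3))
  for (k in seq_along(l3)) {
    ids <- c(ids, l3[k]); nms <- c(nms, sprintf("phenotype group %d", k))
    np <- 1L + (stats::runif(1L) < 0.3)
    parents[[l3[k]]] <- resample(l2, min(np, length(l2)))
  }
  l4 <- sprintf("MP:%07d", 4000L + seq_len(n_l4))
  for (k in seq_along(l4)) {
    ids <- c(ids, l4[k]); nms <- c(nms, sprintf("phenotype %d", k))
    np <- 1L + (stats::runif(1L) < 0.3)
    pr <- resample(l3, min(np, length(l3)))
    # a few terms get an extra level-2 parent: shortest path wins
    if (k %% 17L == 0L) pr <- c(pr, resample(l2, 1L))
    parents[[l4[k]]] <- pr
  }
  l5 <- sprintf("MP:%07d", 5000L + seq_len(n_l5))
  for (k in seq_along(l5)) {
    ids <- c(ids, l5[k]); nms <- c(nms, sprintf("fine phenotype %d", k))
    parents[[l5[k]]] <- resample(l4, 1L)
  }
  ont <- make_ontology(ids, nms, parents)
  attr(ont, "annot_pool") <- setdiff(l4, character(0))
  attr(ont, "normal") <- normal
  attr(ont, "no_abnormal") <- no_abn
  attr(ont, "lethal") <- lethal
  ont
}

# generator-side closure/level bookkeeping (independent of propagate())
sim_closure_counts <- function(ont, terms, levels = c(2L, 3L, 4L)) {
  seen <- character(0)
  stack <- unique(terms)
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, ont$parents[[t]])
  }
  seen <- setdiff(seen, c(ont$root, attr(ont, "no_abnormal")))
  lv <- term_levels(ont)
  vapply(levels, function(k) sum(lv[seen] == k), integer(1L))
}

#' Emit ontology, annotations and gene-class labels
#'
#' Per-gene annotation counts are drawn from group-specific Poisson
#' distributions (`pleiotropy_lambda`); class membership is drawn with the
#' configured class-by-loss odds ratios. `LETHAL` genes additionally carry
#' a direct "prenatal lethality" annotation and `DISPENSABLE` genes are
#' annotated only inside the "normal phenotype" branch, so both labels are
#' re-derivable from the annotations.
#'
#' @param config a [sim_config()].
#' @param lost_any named logical vector over genes (truth: lost in at
#'   least one lineage).
#' @param dir output directory (`pheno.obo`, `annotations.tsv`,
#'   `classes.tsv`) or `NULL`.
#' @return list with `ontology`, `annotations`, `classes` and the ledger
#'   `pheno_counts` (per-gene realized level 2/3/4 counts).
#' @export
emit_ontology_and_classes <- function(config, lost_any, dir = NULL) {
  ont <- build_sim_ontology()
  pool <- attr(ont, "annot_pool")
  genes <- names(lost_any)
  lam <- ifelse(lost_any, config$pleiotropy_lambda[["lost"]],
                config$pleiotropy_lambda[["retained"]])
  has_data <- stats::runif(length(genes)) < config$annotation_coverage
  n_terms <- stats::rpois(length(genes), lam)
  # class draws
  membership <- list()
  for (cl in names(config$class_base_rate)) {
    p0 <- config$class_base_rate[[cl]]
    if (p0 <= 0) { membership[[cl]] <- rep(FALSE, length(genes)); next }
    orr <- config$class_odds_ratio[[cl]]
    odds <- p0 / (1 - p0)
    p1 <- orr * odds / (1 + orr * odds)
    p <- ifelse(lost_any, p1, p0)
    membership[[cl]] <- stats::runif(length(genes)) < p
  }
  # LETHAL and DISPENSABLE must be consistent with annotations
  if (!is.null(membership$LETHAL) && !is.null(membership$DISPENSABLE))
    membership$DISPENSABLE <- membership$DISPENSABLE & !membership$LETHAL
  ann_rows <- new_rows(); count_rows <- new_rows(); class_rows <- new_rows()
  for (k in seq_along(genes)) {
    g <- genes[k]
    for (cl in names(membership))
      if (membership[[cl]][k])
        add_row(class_rows, list(gene_id = g, class = cl))
    if (!has_data[k]) next
    if (!is.null(membership$DISPENSABLE) && membership$DISPENSABLE[k]) {
      terms <- attr(ont, "no_abnormal")
    } else {
      terms <- character(0)
      if (n_terms[k] > 0L)
        terms <- resample(pool, min(n_terms[k], length(pool)))
      if (!is.null(membership$LETHAL) && membership$LETHAL[k])
        terms <- c(terms, attr(ont, "lethal"))
      if (!length(terms)) next
    }
    for (t in terms)
      add_row(ann_rows, list(gene_id = g, term_id = t,
                             genotype_arity = 1L))
    if (stats::runif(1L) < config$digenic_rate)
      add_row(ann_rows, list(gene_id = g, term_id = resample(pool, 1L),
                             genotype_arity = 2L))
    cts <- sim_closure_counts(ont, terms)
    add_row(count_rows, list(
      gene_id = g, level2_count = cts[1L], level3_count = cts[2L],
      level4_count = cts[3L], drawn_count = n_terms[k]))
  }
  annotations <- rows_to_df(ann_rows)
  if (is.null(annotations))
    annotations <- data.frame(gene_id = character(0),
                              term_id = character(0),
                              genotype_arity = integer(0))
  class_df <- rows_to_df(class_rows)
  if (is.null(class_df))
    class_df <- data.frame(gene_id = character(0), class = character(0))
  counts <- rows_to_df(count_rows)
  if (!is.null(dir)) {
    write_obo(ont, file.path(dir, "pheno.obo"))
    write_gene_table(annotations, file.path(dir, "annotations.tsv"))
    write_gene_table(class_df, file.path(dir, "classes.tsv"))
  }
  list(ontology = ont, annotations = annotations, classes = class_df,
       pheno_counts = counts)
}

# ---------------------------------------------------------------------------
# top-level dataset emission

#' Simulate a complete synthetic dataset
#'
#' Writes (under `dir`): `genome.fa`, `genes.bed`, `tree.nwk`,
#' `aln/<species>.maf`, `contexts/<species>.tsv`, `pheno.obo`,
#' `annotations.tsv`, `classes.tsv`, `validation_loci.tsv`,
#' `reads/contigs.fa`, `reads/<locus>.fastq`, `truth_ledger.json` and
#' `sim_config.json`. All randomness is governed by `config$seed`; a rerun
#' with the same configuration is bit-identical.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); `NULL` keeps the
#'   dataset in memory only.
#' @return invisibly, a list with all in-memory components and the
#'   `ledger`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  set.seed(config$seed)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_reference(config)
  hist <- simulate_loss_history(config)
  aln <- emit_alignments(config, ref, hist, dir)
  lost_any <- stats::setNames(hist$n_lineages > 0L, rownames(hist$truth))
  onto <- emit_ontology_and_classes(config, lost_any, dir)
  genes_df <- data.frame(
    gene_id = vapply(ref$models, `[[`, character(1L), "gene_id"),
    transcript_id = vapply(ref$models, `[[`, character(1L),
                           "transcript_id"),
    n_codons = vapply(ref$models, n_codons, integer(1L)),
    n_exons = vapply(ref$models, function(m) nrow(m$exons), integer(1L)),
    n_lineages = hist$n_lineages,
    event_branches = vapply(hist$event_branches, paste, character(1L),
                            collapse = ","),
    stringsAsFactors = FALSE)
  ledger <- list(
    summary = list(
      n_genes = config$n_genes,
      n_species = config$n_species,
      n_lost_any = sum(hist$n_lineages > 0L),
      n_single_lineage = sum(hist$n_lineages == 1L),
      n_multi_lineage = sum(hist$n_lineages >= 2L)),
    genes = genes_df,
    calls = aln$calls,
    mutations = aln$mutations,
    classes = onto$classes,
    pheno_counts = onto$pheno_counts,
    loci = aln$loci)
  if (!is.null(dir)) {
    write_fasta(ref$genome, file.path(dir, "genome.fa"))
    write_gene_models_bed(ref$models, file.path(dir, "genes.bed"))
    write_newick(hist$tree, file.path(dir, "tree.nwk"))
    jsonlite::write_json(ledger, file.path(dir, "truth_ledger.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    cfg <- unclass(config)
    cfg$tree <- NULL
    jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(config = config, reference = ref, history = hist,
                 alignments = aln, ontology = onto, ledger = ledger))
}
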