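# Fixture builders and independent oracles, all constructed in code.

# --- toy gene models -------------------------------------------------------

# deterministic CDS with no internal stop codons: atg + repeated non-stop
# codons + terminal taa, split into exons of the given codon counts
toy_exon_seqs <- function(codons_per_exon) {
  L <- sum(codons_per_exon)
  cod <- c("atg", rep(c("gca", "gtt", "cta", "gaa", "ttc"),
                      length.out = L - 2L), "taa")
  s <- paste(cod, collapse = "")
  offs <- cumsum(c(0L, codons_per_exon * 3L))
  substring(s, offs[-length(offs)] + 1L, offs[-1L])
}

toy_model <- function(codons_per_exon, gene = "G1", tx = "G1.T1",
                      chrom = "chr1", start = 100L) {
  lens <- as.integer(codons_per_exon * 3L)
  starts <- start + cumsum(c(0L, utils::head(lens, -1L) + 30L))
  gene_model(gene, tx, chrom, "+",
             cbind(start = starts, end = starts + lens))
}

# per-exon alignment record list; query defaults to the reference, splice
# dinucleotides default to intact gt/ag on internal boundaries
make_recs <- function(model, q_exons = NULL, ref_exons = NULL,
                      donors = NULL, acceptors = NULL, species = "spX",
                      skip = integer(0)) {
  n <- nrow(model$exons)
  lens <- model$exons[, "end"] - model$exons[, "start"]
  if (is.null(ref_exons)) stop("ref_exons required")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %in% skip) next
    recs[[i]] <- genelossr:::exon_alignment(
      model$gene_id, model$transcript_id, i - 1L, species, "ALIGNED",
      ref_aln = ref_exons[i],
      query_aln = if (is.null(q_exons)) ref_exons[i] else q_exons[i],
      query_donor = if (i < n) (donors %||% rep("gt", n))[i]
      else NA_character_,
      query_acceptor = if (i > 1L) (acceptors %||% rep("ag", n))[i]
      else NA_character_,
      ref_donor = if (i < n) "gt" else NA_character_,
      ref_acceptor = if (i > 1L) "ag" else NA_character_)
  }
  recs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replace the codon at 1-based CDS codon position `c0` in a set of exon
# strings (codon must lie fully within one exon)
put_codon <- function(exon_seqs, codons_per_exon, c0, codon) {
  offs <- cumsum(c(0L, codons_per_exon * 3L))
  e <- findInterval(3L * (c0 - 1L), offs[-length(offs)])
  p <- 3L * (c0 - 1L) - offs[e] + 1L
  substr(exon_seqs[e], p, p + 2L) <- codon
  exon_seqs
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

rand_dna_test <- function(n)
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")

# --- Dollo brute-force oracle ---------------------------------------------

# minimal Dollo event placement by exhaustive search over subsets of
# candidate branches; among minimum-cardinality valid subsets the most
# ancestral placement (largest total subtended leaf count) is returned
dollo_oracle <- function(tree, states) {
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  leaves <- vector("list", ntot)
  get_leaves <- function(v) {
    if (!is.null(leaves[[v]])) return(leaves[[v]])
    r <- if (v <= n) v else
      unlist(lapply(kids[[as.character(v)]], get_leaves))
    leaves[[v]] <<- r
    r
  }
  for (v in seq_len(ntot)) get_leaves(v)
  st <- states[tree$tip.label]
  lost <- which(!is.na(st) & st == "LOST")
  intact <- which(!is.na(st) & st == "INTACT")
  if (!length(lost)) return(integer(0))
  cand <- which(vapply(seq_len(ntot), function(v)
    !any(leaves[[v]] %in% intact) && any(leaves[[v]] %in% lost),
    logical(1L)))
  best <- NULL; best_size <- Inf; best_cov <- -1L
  for (mask in seq_len(2^length(cand)) - 1L) {
    sel <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1L)) > 0L]
    if (length(sel) > best_size) next
    covered <- unique(unlist(leaves[sel]))
    if (!all(lost %in% covered)) next
    cov <- sum(lengths(leaves[sel]))
    if (length(sel) < best_size ||
        (length(sel) == best_size && cov > best_cov)) {
      best <- sel; best_size <- length(sel); best_cov <- cov
    }
  }
  sort(best)
}

# random rooted tree with optional multifurcations
random_tree <- function(n, multifurcate = FALSE) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  if (multifurcate && n > 3L) tr <- ape::di2multi(tr, tol = 0.4)
  tr
}

random_states <- function(tree, p_lost = 0.4, p_na = 0.15) {
  n <- ape::Ntip(tree)
  r <- runif(n)
  st <- ifelse(r < p_lost, "LOST", ifelse(r < p_lost + p_na, NA, "INTACT"))
  names(st) <- tree$tip.label
  st
}

# --- ontology oracles ------------------------------------------------------

# random layered-ish DAG: term i may take parents among earlier terms
random_dag <- function(n_terms) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- list(); parents[[ids[1L]]] <- character(0)
  for (i in seq(2L, n_terms)) {
    np <- sample(1:2, 1L)
    parents[[ids[i]]] <- unique(sample(ids[seq_len(i - 1L)],
                                       min(np, i - 1L)))
  }
  genelossr:::make_ontology(ids, ids, parents)
}

# brute-force ancestor closure by repeated expansion of the parent sets
closure_oracle <- function(ont, terms) {
  seen <- unique(terms)
  repeat {
    nxt <- unique(c(seen, unlist(ont$parents[seen])))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  sort(setdiff(seen, ont$root))
}

# brute-force shortest-path level (root = 1) by path enumeration
level_oracle <- function(ont, term) {
  if (term == ont$root) return(1L)
  best <- Inf
  walk <- function(t, d) {
    if (t == ont$root) { best <<- min(best, d); return(invisible()) }
    for (p in ont$parents[[t]]) walk(p, d + 1L)
  }
  walk(term, 0L)
  as.integer(best + 1L)
}

# --- statistical oracles ---------------------------------------------------

# exact two-sided Wilcoxon p by enumeration of all group assignments
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-corrected normal approximation with continuity correction
wilcox_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2)
  z <- (abs(z) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-z)
}

# exact-integer hypergeometric enumeration (valid while choose() values
# stay below 2^53, i.e. N <= 20): two-sided p as a ratio of integers
fisher_rational_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  supp <- max(0L, r1 + c1 - N):min(r1, c1)
  w <- choose(c1, supp) * choose(N - c1, r1 - supp)  # integer-valued
  w_obs <- w[match(a, supp)]
  sum(w[w <= w_obs]) / sum(w)
}

# --- misc ------------------------------------------------------------------

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
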