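# Depletion/enrichment of gene classes among lost genes.
#
# Lost genes are compared against never-lost genes for membership in the
# disease / essential / lethal / dispensable classes with two-sided
# Fisher's exact tests on 2x2 tables. The two-sided p-value follows the
# "probability mass <= observed" rule: the sum of hypergeometric
# probabilities (margins fixed) of all tables at most as probable as the
# observed one. The odds ratio is the sample cross-product (a*d)/(b*c),
# with Inf when only b*c is zero and NaN when both products are zero.

GENE_CLASSES <- c("DISEASE", "ESSENTIAL", "LETHAL", "DISPENSABLE")

#' Two-sided Fisher's exact test
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio` (sample cross-product) and `p` (two-sided,
#'   probability-mass rule).
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stopf("table must be a 2x2 matrix")
  x <- as.vector(table)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stopf("table cells must be non-negative integers")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  or <- if (b * c_ > 0) (a * d) / (b * c_)
  else if (a * d > 0) Inf else NaN
  if (N == 0L) return(list(odds_ratio = or, p = 1))
  supp <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(supp, c1, N - c1, r1)
  p_obs <- probs[match(a, supp)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Class enrichment/depletion among lost genes
#'
#' For each gene class, compares class membership between a loss group and
#' the no-loss background with a two-sided Fisher's exact test. Comparisons
#' are run for the single-lineage and multi-lineage groups separately and
#' for the pooled lost group (`lost_any`). Per-bar percentages (share of
#' each partition group belonging to the class) are reported alongside.
#'
#' @param partition list with gene-id vectors `not_lost`, `single_lineage`,
#'   `multi_lineage` (from [partition_by_lineage_count()]).
#' @param classes data.frame with columns `gene_id`, `class` (one row per
#'   membership; a gene may carry several classes).
#' @param universe character vector of all screened genes; defaults to the
#'   union of the partition.
#' @param class_names classes to test (default all four).
#' @param holm apply a Holm adjustment across the reported p-values
#'   (default FALSE: per-comparison tests).
#' @return data.frame with one row per class x comparison: 2x2 cells, odds
#'   ratio, p, direction (`DEPLETED` if OR < 1, `ENRICHED` if OR > 1,
#'   `NONE` otherwise) and the group/background class percentages.
#' @export
class_enrichment <- function(partition, classes, universe = NULL,
                             class_names = GENE_CLASSES, holm = FALSE) {
  universe <- universe %||%
    unique(unlist(partition[c("not_lost", "single_lineage",
                              "multi_lineage")]))
  bad <- setdiff(unique(classes$class), GENE_CLASSES)
  if (length(bad))
    stopf("unknown gene class label(s): %s", paste(bad, collapse = ", "))
  groups <- list(single_lineage = partition$single_lineage,
                 multi_lineage = partition$multi_lineage,
                 lost_any = union(partition$single_lineage,
                                  partition$multi_lineage))
  background <- intersect(partition$not_lost, universe)
  rows <- list()
  for (cl in class_names) {
    members <- unique(classes$gene_id[classes$class == cl])
    for (gname in names(groups)) {
      grp <- intersect(groups[[gname]], universe)
      a <- sum(grp %in% members)
      b <- length(grp) - a
      c_ <- sum(background %in% members)
      d <- length(background) - c_
      ft <- fisher_exact_two_sided(rbind(c(a, b), c(c_, d)))
      dir <- if (is.nan(ft$odds_ratio) || ft$odds_ratio == 1) "NONE"
      else if (ft$odds_ratio < 1) "DEPLETED" else "ENRICHED"
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, group = gname,
        in_class_in_group = a, not_class_in_group = b,
        in_class_background = c_, not_class_background = d,
        pct_group = if (a + b > 0) 100 * a / (a + b) else NA_real_,
        pct_background = if (c_ + d > 0) 100 * c_ / (c_ + d) else NA_real_,
        odds_ratio = ft$odds_ratio, p_value = ft$p, direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}

#' Derive lethal/dispensable labels from phenotype annotations
#'
#' `LETHAL`: genes whose closed annotation set contains the "prenatal
#' lethality" term. `DISPENSABLE`: genes annotated only within the "normal
#' phenotype" branch of the ontology (no closed term outside that branch).
#'
#' @param closures named list from [propagate()].
#' @param ont an `ontology` containing terms named "prenatal lethality" and
#'   "normal phenotype".
#' @return data.frame (`gene_id`, `class`) appendable to a class table.
#' @export
derive_class_labels <- function(closures, ont) {
  lethal_id <- ont$terms$id[ont$terms$name == "prenatal lethality"]
  normal_id <- ont$terms$id[ont$terms$name == "normal phenotype"]
  rows <- list()
  normal_branch <- if (length(normal_id))
    c(normal_id, names(Filter(function(x) x,
        vapply(ont$terms$id, function(t)
          normal_id %in% term_ancestors(ont, t), logical(1L)))))
  else character(0)
  for (g in names(closures)) {
    terms <- closures[[g]]
    if (length(lethal_id) && lethal_id %in% terms)
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, class = "LETHAL",
                                              stringsAsFactors = FALSE)
    if (length(normal_branch) && length(terms) &&
        all(terms %in% normal_branch))
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g,
                                              class = "DISPENSABLE",
                                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
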