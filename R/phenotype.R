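# Knockout-phenotype pleiotropy via ontology propagation.
#
# Direct gene->phenotype annotations (from single-gene knockouts only) are
# propagated up the is_a hierarchy; the number of distinct terms a gene
# reaches at a fixed ontology level (2, 3 or 4) is its pleiotropy score at
# that level. The "no abnormal phenotype detected" term is excluded from
# counting by default. When a term is reachable at several depths its level
# is the minimum depth (shortest path), so each term counts at exactly one
# level.

#' Keep only single-gene knockout annotations
#'
#' @param annotations data.frame with columns `gene_id`, `term_id`,
#'   `genotype_arity` (number of genes in the knockout genotype).
#' @return the subset with `genotype_arity == 1`.
#' @export
filter_single_gene_knockouts <- function(annotations) {
  need <- c("gene_id", "term_id", "genotype_arity")
  if (!all(need %in% names(annotations)))
    stopf("annotations must have columns %s", paste(need, collapse = ", "))
  out <- annotations[annotations$genotype_arity == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply an ortholog mapping to an annotation table
#'
#' Replaces annotation gene identifiers by their one-to-one orthologs in
#' the reference gene space (rows without a mapping are dropped).
#'
#' @param annotations annotation data.frame (`gene_id`, ...).
#' @param map data.frame with columns `from`, `to`, or `NULL` for identity.
#' @return the remapped annotation data.frame.
#' @export
apply_ortholog_map <- function(annotations, map = NULL) {
  if (is.null(map)) return(annotations)
  idx <- match(annotations$gene_id, map$from)
  keep <- !is.na(idx)
  out <- annotations[keep, , drop = FALSE]
  out$gene_id <- map$to[idx[keep]]
  rownames(out) <- NULL
  out
}

#' Propagate annotations up the ontology
#'
#' Closes each gene's direct term set under is_a ancestors (transitive
#' closure); the root term is excluded from the result so it never enters
#' any count.
#'
#' @param annotations data.frame (`gene_id`, `term_id`) of direct
#'   annotations, or a named list gene -> character vector of terms.
#' @param ont an `ontology` from [read_obo()].
#' @return named list gene -> sorted character vector of closed terms.
#' @export
propagate <- function(annotations, ont) {
  direct <- if (is.data.frame(annotations))
    split(annotations$term_id, annotations$gene_id)
  else annotations
  unknown <- setdiff(unique(unlist(direct)), ont$terms$id)
  if (length(unknown))
    stopf("annotation term(s) not in ontology: %s",
          paste(utils::head(unknown, 3L), collapse = ", "))
  lapply(direct, function(terms) {
    terms <- unique(terms)
    closed <- unique(c(terms, unlist(lapply(terms, term_ancestors,
                                            ont = ont))))
    sort(setdiff(closed, ont$root))
  })
}

#' Default excluded terms
#'
#' Terms excluded from pleiotropy counting: by default the single
#' "no abnormal phenotype detected" term, located by name.
#'
#' @param ont an `ontology`.
#' @return character vector of term ids (possibly empty).
#' @export
default_excluded_terms <- function(ont) {
  ont$terms$id[ont$terms$name == "no abnormal phenotype detected"]
}

#' Count phenotypes of one gene at an ontology level
#'
#' @param closed_terms character vector of the gene's closed (propagated)
#'   terms.
#' @param ont an `ontology`.
#' @param level ontology level to count at (2, 3 or 4).
#' @param excluded_terms term ids never counted; defaults to the
#'   no-abnormal-phenotype term.
#' @return non-negative integer.
#' @export
count_phenotypes <- function(closed_terms, ont, level,
                             excluded_terms = default_excluded_terms(ont)) {
  lv <- term_levels(ont)
  keep <- setdiff(closed_terms, c(excluded_terms, ont$root))
  sum(lv[keep] == level, na.rm = TRUE)
}

#' Per-gene phenotype counts at levels 2, 3 and 4
#'
#' @param closures named list from [propagate()].
#' @param ont an `ontology`.
#' @param levels integer vector of levels.
#' @param excluded_terms see [count_phenotypes()].
#' @param drop_empty drop genes whose closure is empty after exclusions
#'   (default TRUE; set FALSE to keep them with zero counts).
#' @return data.frame `gene_id`, `level<k>_count` columns.
#' @export
count_phenotype_levels <- function(closures, ont, levels = c(2L, 3L, 4L),
                                   excluded_terms =
                                     default_excluded_terms(ont),
                                   drop_empty = TRUE) {
  lv <- term_levels(ont)
  rows <- lapply(names(closures), function(g) {
    keep <- setdiff(closures[[g]], c(excluded_terms, ont$root))
    if (drop_empty && !length(keep)) return(NULL)
    counts <- vapply(levels, function(k) sum(lv[keep] == k, na.rm = TRUE),
                     integer(1L))
    df <- data.frame(gene_id = g, stringsAsFactors = FALSE)
    df[paste0("level", levels, "_count")] <- as.list(counts)
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0))
    out[paste0("level", levels, "_count")] <-
      rep(list(integer(0)), length(levels))
  }
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper with the conventions used throughout: exact p-value when the
#' smaller group has at most `exact_max` observations and the pooled data
#' are tie-free, otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction. Also reports the
#' rank-biserial correlation (positive when `x` tends larger than `y`).
#'
#' @param x,y numeric vectors.
#' @param exact_max largest min-group size for which the exact distribution
#'   is used (default 25).
#' @return list with `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `method`, `rank_biserial`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  U <- unname(wt$statistic)
  list(statistic = U, p_value = unname(wt$p.value),
       method = if (exact) "exact" else "normal_tie_corrected",
       rank_biserial = 2 * U / (length(x) * length(y)) - 1)
}

#' Compare pleiotropy between loss groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of per-gene phenotype counts
#' between groups (typically no-loss / single-lineage / multi-lineage).
#'
#' @param group_counts named list of numeric vectors (per-gene counts per
#'   group); at least two nonempty groups.
#' @return data.frame with one row per group pair: sizes, medians, U,
#'   two-sided p, rank-biserial effect and its direction.
#' @export
pleiotropy_compare <- function(group_counts) {
  group_counts <- Filter(length, group_counts)
  if (length(group_counts) < 2L)
    stopf("need at least two nonempty groups")
  nms <- names(group_counts)
  pairs <- utils::combn(seq_along(group_counts), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    w <- wilcoxon_rank_sum(group_counts[[i]], group_counts[[j]])
    data.frame(group1 = nms[i], group2 = nms[j],
               n1 = length(group_counts[[i]]),
               n2 = length(group_counts[[j]]),
               median1 = stats::median(group_counts[[i]]),
               median2 = stats::median(group_counts[[j]]),
               U = w$statistic, p_value = w$p_value, method = w$method,
               rank_biserial = w$rank_biserial,
               direction = if (w$rank_biserial > 0) "GROUP1_HIGHER"
               else if (w$rank_biserial < 0) "GROUP2_HIGHER" else "NONE",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
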