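# Dollo parsimony on binary gene presence/absence characters.
#
# An intact gene is a complex character that is never regained once lost:
# losses observed in sister species are explained by a single event on the
# branch to their common ancestor. Leaves with no data (NA) are transparent:
# a subtree counts as all-lost when every non-NA leaf in it is lost and it
# contains at least one lost leaf, so a missing genome never breaks
# ancestral grouping. The inferred event branches are the maximal all-lost
# subtrees; their count is the number of independent loss lineages.
# Multifurcations are handled by the same rule (grouping at a multifurcating
# ancestor requires all its child subtrees to qualify), and the root branch
# is a legal event branch.

node_labels_or_default <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs) || !length(labs) || any(!nzchar(labs)))
    labs <- paste0("node", seq_len(nn))
  c(tree$tip.label, labs)
}

#' Infer loss events on a species tree under Dollo parsimony
#'
#' @param tree an `ape::phylo` rooted tree.
#' @param leaf_states named character vector over the tree's leaves with
#'   values `"LOST"`, `"INTACT"` or `NA` (missing genome/region).
#' @param gene_id identifier carried through to the result.
#' @return an object of class `loss_history`: list with `gene_id`, `tree`,
#'   `leaf_states`, `event_nodes` (internal ape node numbers of the child
#'   ends of event branches), `event_branches` (their labels),
#'   `n_independent_lineages`.
#' @export
infer_loss_events <- function(tree, leaf_states, gene_id = "gene") {
  n <- ape::Ntip(tree)
  if (is.null(names(leaf_states)))
    stopf("leaf_states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(leaf_states))
  if (length(miss))
    stopf("leaf_states missing for: %s", paste(miss, collapse = ", "))
  st <- leaf_states[tree$tip.label]
  bad <- !is.na(st) & !st %in% c("LOST", "INTACT")
  if (any(bad)) stopf("invalid leaf state: %s", st[bad][1L])
  ntot <- n + tree$Nnode
  lost <- integer(ntot); intact <- integer(ntot)
  lost[seq_len(n)] <- as.integer(!is.na(st) & st == "LOST")
  intact[seq_len(n)] <- as.integer(!is.na(st) & st == "INTACT")
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; c_ <- edge[k, 2L]
    lost[p] <- lost[p] + lost[c_]
    intact[p] <- intact[p] + intact[c_]
  }
  qualifies <- intact == 0L & lost > 0L
  parent <- rep(NA_integer_, ntot)
  parent[edge[, 2L]] <- edge[, 1L]
  root <- n + 1L
  parent_q <- !is.na(parent) & qualifies[ifelse(is.na(parent), 1L, parent)]
  events <- which(qualifies & !parent_q)
  labs <- node_labels_or_default(tree)
  structure(list(gene_id = gene_id, tree = tree, leaf_states = st,
                 event_nodes = events, event_branches = labs[events],
                 n_independent_lineages = length(events)),
            class = "loss_history")
}

#' @export
print.loss_history <- function(x, ...) {
  cat(sprintf("<loss_history> %s: %d lost leaf(s), %d independent lineage(s) [%s]\n",
              x$gene_id, sum(!is.na(x$leaf_states) & x$leaf_states == "LOST"),
              x$n_independent_lineages,
              paste(x$event_branches, collapse = ", ")))
  invisible(x)
}

#' Loss histories for every gene of a loss matrix
#'
#' @param mat gene x species matrix from [build_loss_matrix()].
#' @param tree an `ape::phylo` whose tip labels are the matrix columns.
#' @return named list of `loss_history` objects (genes with at least one
#'   LOST cell; others get an empty history with 0 lineages).
#' @export
loss_histories <- function(mat, tree) {
  if (!all(colnames(mat) %in% tree$tip.label))
    stopf("loss matrix columns not all present in tree")
  out <- vector("list", nrow(mat))
  names(out) <- rownames(mat)
  for (g in rownames(mat)) {
    st <- mat[g, ]
    if (!any(!is.na(st) & st == "LOST")) {
      out[[g]] <- structure(
        list(gene_id = g, tree = tree, leaf_states = st,
             event_nodes = integer(0), event_branches = character(0),
             n_independent_lineages = 0L),
        class = "loss_history")
    } else {
      out[[g]] <- infer_loss_events(tree, st, g)
    }
  }
  out
}

#' Partition genes by independent-lineage count
#'
#' @param histories named list of `loss_history` objects (all genes).
#' @return list of three disjoint character vectors covering all genes:
#'   `not_lost` (0 lineages), `single_lineage` (1), `multi_lineage` (>= 2).
#' @export
partition_by_lineage_count <- function(histories) {
  k <- vapply(histories, `[[`, integer(1L), "n_independent_lineages")
  list(not_lost = names(k)[k == 0L],
       single_lineage = names(k)[k == 1L],
       multi_lineage = names(k)[k >= 2L])
}

#' Per-gene lineage table
#'
#' @param histories named list of `loss_history` objects.
#' @return data.frame (gene_id, n_independent_lineages, event_branches as a
#'   comma-separated label list).
#' @export
lineage_table <- function(histories) {
  data.frame(
    gene_id = vapply(histories, `[[`, character(1L), "gene_id"),
    n_independent_lineages = vapply(histories, `[[`, integer(1L),
                                    "n_independent_lineages"),
    event_branches = vapply(histories, function(h)
      paste(h$event_branches, collapse = ","), character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}
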