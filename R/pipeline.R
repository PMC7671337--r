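# End-to-end orchestration: scan -> classify -> Dollo -> pleiotropy ->
# enrichment -> read validation, with deterministic TSV/JSON outputs.
# Stage outputs are pure functions of (inputs, thresholds): reruns are
# byte-identical.

#' Run the gene-loss analysis pipeline
#'
#' Expects an input directory in the layout written by
#' [simulate_dataset()] (`genes.bed`, `tree.nwk`, `aln/<species>.maf`,
#' `contexts/<species>.tsv`, optionally `pheno.obo` + `annotations.tsv`,
#' `classes.tsv`, `validation_loci.tsv` + `reads/`), which is also the
#' ingestion contract for real data. Writes per-stage TSVs and a
#' `summary.json` into `out_dir`.
#'
#' @param input_dir input directory.
#' @param out_dir output directory (created).
#' @param thresholds a [loss_thresholds()].
#' @param rule intact-fraction rule, see [intact_fraction()].
#' @param stages character subset of
#'   `c("scan", "classify", "dollo", "pleiotropy", "enrich", "validate")`;
#'   later stages require earlier ones.
#' @param ortholog_map optional data.frame (`from`, `to`) applied to the
#'   annotation gene ids.
#' @return invisibly, a list with all stage results and the `summary`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         thresholds = loss_thresholds(),
                         rule = "terminal_flank",
                         stages = c("scan", "classify", "dollo",
                                    "pleiotropy", "enrich", "validate"),
                         ortholog_map = NULL) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tick <- function(name) {
    log_stage("%-10s done (%.1f s elapsed)", name,
              proc.time()[["elapsed"]] - t0)
  }
  models <- read_gene_models(file.path(input_dir, "genes.bed"))
  tree <- read_newick(file.path(input_dir, "tree.nwk"))
  res <- list()
  summary <- list(n_genes = length(unique(
    vapply(models, `[[`, character(1L), "gene_id"))))

  maf_files <- sort(list.files(file.path(input_dir, "aln"),
                               pattern = "\\.maf$", full.names = TRUE))
  species <- sub("\\.maf$", "", basename(maf_files))
  summary$n_species <- length(species)

  if ("scan" %in% stages) {
    muts <- list(); scans <- list()
    for (k in seq_along(species)) {
      sp <- species[k]
      alns <- read_exon_alignments(maf_files[k], models)
      ctx_file <- file.path(input_dir, "contexts", paste0(sp, ".tsv"))
      ctx <- if (file.exists(ctx_file)) read_contexts(ctx_file) else NULL
      scans[[sp]] <- scan_species(models, alns, ctx, sp, thresholds)
      muts[[sp]] <- scans[[sp]]$mutations
    }
    res$mutations <- do.call(rbind, c(muts, make.row.names = FALSE))
    write_gene_table(res$mutations, file.path(out_dir, "mutations.tsv"))
    res$scans <- scans
    summary$n_mutations <- nrow(res$mutations)
    tick("scan")
  }

  if ("classify" %in% stages) {
    calls <- lapply(species, function(sp)
      classify_species(models, res$scans[[sp]], sp, thresholds, rule))
    res$loss_calls <- do.call(rbind, c(calls, make.row.names = FALSE))
    write_gene_table(res$loss_calls, file.path(out_dir, "loss_calls.tsv"))
    res$loss_matrix <- build_loss_matrix(res$loss_calls)
    write_loss_matrix(res$loss_matrix, file.path(out_dir,
                                                 "loss_matrix.tsv"))
    summary$n_lost_calls <- sum(res$loss_calls$lost, na.rm = TRUE)
    tick("classify")
  }

  if ("dollo" %in% stages) {
    res$histories <- loss_histories(res$loss_matrix, tree)
    res$lineages <- lineage_table(res$histories)
    write_gene_table(res$lineages, file.path(out_dir, "lineages.tsv"))
    res$partition <- partition_by_lineage_count(res$histories)
    summary$n_lost_any <- length(res$partition$single_lineage) +
      length(res$partition$multi_lineage)
    summary$n_single_lineage <- length(res$partition$single_lineage)
    summary$n_multi_lineage <- length(res$partition$multi_lineage)
    summary$pct_lost <- round(100 * summary$n_lost_any /
                                summary$n_genes, 4)
    summary$pct_multi_among_lost <- if (summary$n_lost_any > 0)
      round(100 * summary$n_multi_lineage / summary$n_lost_any, 4)
    else NA
    tick("dollo")
  }

  obo_file <- file.path(input_dir, "pheno.obo")
  if ("pleiotropy" %in% stages && file.exists(obo_file)) {
    ont <- read_obo(obo_file)
    ann <- read_gene_table(file.path(input_dir, "annotations.tsv"))
    ann <- filter_single_gene_knockouts(ann)
    ann <- apply_ortholog_map(ann, ortholog_map)
    closures <- propagate(ann, ont)
    res$pheno_counts <- count_phenotype_levels(closures, ont)
    write_gene_table(res$pheno_counts,
                     file.path(out_dir, "pheno_counts.tsv"))
    tests <- list()
    for (lev in c(2L, 3L, 4L)) {
      col <- paste0("level", lev, "_count")
      groups <- lapply(res$partition[c("not_lost", "single_lineage",
                                       "multi_lineage")], function(gs) {
        res$pheno_counts[[col]][res$pheno_counts$gene_id %in% gs]
      })
      groups <- Filter(length, groups)
      if (length(groups) >= 2L) {
        tt <- pleiotropy_compare(groups)
        tt$level <- lev
        tests[[length(tests) + 1L]] <- tt
      }
    }
    res$pleiotropy_tests <- do.call(rbind, tests)
    if (!is.null(res$pleiotropy_tests))
      write_gene_table(res$pleiotropy_tests,
                       file.path(out_dir, "pleiotropy_tests.tsv"))
    tick("pleiotropy")
  }

  class_file <- file.path(input_dir, "classes.tsv")
  if ("enrich" %in% stages && file.exists(class_file)) {
    classes <- read_gene_table(class_file)
    res$enrichment <- class_enrichment(res$partition, classes)
    write_gene_table(res$enrichment, file.path(out_dir, "enrichment.tsv"))
    pooled <- res$enrichment[res$enrichment$group == "lost_any", ]
    summary$class_odds_ratios <- stats::setNames(
      as.list(pooled$odds_ratio), pooled$class)
    summary$class_p_values <- stats::setNames(
      as.list(pooled$p_value), pooled$class)
    tick("enrich")
  }

  loci_file <- file.path(input_dir, "validation_loci.tsv")
  if ("validate" %in% stages && file.exists(loci_file)) {
    loci <- read_gene_table(loci_file)
    res$validation <- validate_mutations(
      loci, file.path(input_dir, "reads", "contigs.fa"),
      file.path(input_dir, "reads"), thresholds)
    write_gene_table(res$validation, file.path(out_dir, "validation.tsv"))
    summary$n_loci_validated <- nrow(res$validation)
    summary$n_confirmed <- sum(res$validation$status == "CONFIRMED")
    tick("validate")
  }

  res$summary <- summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(res)
}
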