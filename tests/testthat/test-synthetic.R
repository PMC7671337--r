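# The synthetic-data generator and its truth ledger.

test_that("loss histories honour the configured rates", {
  cfg0 <- sim_config(seed = 71, n_genes = 150, branch_loss_prob = 0)
  set.seed(cfg0$seed)
  h0 <- simulate_loss_history(cfg0)
  expect_true(all(h0$truth == "INTACT"))
  expect_true(all(h0$n_lineages == 0L))
  # convergence 0: every lost gene has exactly one event branch
  cfg1 <- sim_config(seed = 72, n_genes = 400, branch_loss_prob = 0.08,
                     convergence_rate = 0)
  set.seed(cfg1$seed)
  h1 <- simulate_loss_history(cfg1)
  lost <- h1$n_lineages[apply(h1$truth == "LOST", 1L, any)]
  expect_gt(length(lost), 0L)
  expect_true(all(lost == 1L))
  # histories are Dollo-consistent: the inference engine never needs more
  # events than the generator placed
  for (g in sample(which(h1$n_lineages > 0L), 20L)) {
    st <- h1$truth[g, ]
    k <- infer_loss_events(h1$tree, st)$n_independent_lineages
    expect_equal(k, h1$n_lineages[g])
  }
})

test_that("multi-lineage fraction matches exact enumeration on a star tree", {
  # on a star tree every branch is independent, so the sequential
  # first-event/convergence scheme can be enumerated exactly
  star <- ape::read.tree(text = "(A,B,C,D,E,F,G,H);")
  p <- 0.05; cv <- 0.10
  probs <- numeric(3L)   # P(0 events), P(1 event), P(>=2 events)
  recurse <- function(k, has_event, n_events, acc) {
    if (k > 8L) {
      idx <- min(n_events, 2L) + 1L
      probs[idx] <<- probs[idx] + acc
      return(invisible())
    }
    pr <- if (has_event) cv else p
    recurse(k + 1L, TRUE, n_events + 1L, acc * pr)
    recurse(k + 1L, has_event, n_events, acc * (1 - pr))
  }
  recurse(1L, FALSE, 0L, 1)
  exp_multi_given_lost <- probs[3L] / (probs[2L] + probs[3L])
  cfg <- sim_config(seed = 73, n_genes = 2000, tree = star,
                    branch_loss_prob = p, convergence_rate = cv)
  set.seed(cfg$seed)
  h <- simulate_loss_history(cfg)
  n_lost <- sum(h$n_lineages > 0L)
  n_multi <- sum(h$n_lineages >= 2L)
  ci <- stats::binom.test(n_multi, n_lost,
                          p = exp_multi_given_lost)$p.value
  expect_gt(ci, 0.001)
})

test_that("noise-free intact genes align identically to the reference", {
  cfg <- sim_config(seed = 74, n_genes = 15, n_species = 2,
                    branch_loss_prob = 0, syn_sub_rate = 0,
                    inframe_del_rate = 0, assembly_gap_rate = 0,
                    na_rate = 0)
  d <- simulate_dataset(cfg)
  for (sp in names(d$alignments$per_species)) {
    b <- d$alignments$per_species[[sp]]$blocks
    expect_identical(b$ref_text, b$q_text)
  }
})

test_that("the ledger round-trips through the scanner", {
  # single-exon genes receive two point mutations; the scanner sees both
  cfg <- sim_config(seed = 75, n_genes = 60, n_species = 4,
                    n_exons_range = c(1L, 1L), na_rate = 0,
                    assembly_gap_rate = 0)
  dir <- withr::local_tempdir()
  d <- simulate_dataset(cfg, dir)
  expect_false(is.null(d$ledger$mutations))
  led <- d$ledger$mutations
  n_by_pair <- tapply(led$kind, paste(led$gene_id, led$species),
                      function(k) if (any(k == "GENE_DELETED")) 2L
                      else length(k))
  expect_true(all(n_by_pair == 2L))   # two hits, or one whole-gene loss
  models <- read_gene_models(file.path(dir, "genes.bed"))
  sp <- colnames(d$history$truth)[1L]
  alns <- read_exon_alignments(file.path(dir, "aln",
                                         paste0(sp, ".maf")), models)
  ctx <- read_contexts(file.path(dir, "contexts", paste0(sp, ".tsv")))
  scan <- scan_species(models, alns, ctx, sp)
  inj <- d$ledger$mutations[d$ledger$mutations$species == sp, ]
  key <- function(df)
    sort(paste(df$gene_id, df$kind, df$exon_index, df$codon_position))
  expect_equal(key(scan$mutations), key(inj))
})

test_that("emission is reproducible bit for bit", {
  cfg <- sim_config(seed = 76, n_genes = 25, n_species = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(md5_of_dir(d1), md5_of_dir(d2))
  # a different seed changes the data
  simulate_dataset(sim_config(seed = 77, n_genes = 25, n_species = 3), d2)
  expect_false(identical(md5_of_dir(d1), md5_of_dir(d2)))
})

test_that("ontology emission encodes classes consistently with labels", {
  cfg <- sim_config(seed = 78, n_genes = 400)
  set.seed(cfg$seed)
  lost_any <- setNames(runif(400) < 0.3, sprintf("G%04d", 1:400))
  o <- emit_ontology_and_classes(cfg, lost_any)
  # the no-abnormal-phenotype term is attached to dispensable genes only,
  # so DISPENSABLE re-derives from the annotations
  ann <- filter_single_gene_knockouts(o$annotations)
  cl <- propagate(ann, o$ontology)
  derived <- derive_class_labels(cl, o$ontology)
  want_disp <- sort(o$classes$gene_id[o$classes$class == "DISPENSABLE" &
                                        o$classes$gene_id %in% names(cl)])
  expect_equal(sort(derived$gene_id[derived$class == "DISPENSABLE"]),
               want_disp)
  # lethal labels re-derive likewise
  want_leth <- sort(intersect(
    o$classes$gene_id[o$classes$class == "LETHAL"], names(cl)))
  expect_equal(sort(derived$gene_id[derived$class == "LETHAL"]), want_leth)
  # ledger counts match the pipeline-side propagation
  counts <- count_phenotype_levels(cl, o$ontology)
  merged <- merge(counts, o$pheno_counts, by = "gene_id")
  expect_gt(nrow(merged), 100L)
  expect_equal(merged$level2_count.x, merged$level2_count.y)
  expect_equal(merged$level3_count.x, merged$level3_count.y)
  expect_equal(merged$level4_count.x, merged$level4_count.y)
})

test_that("read emission respects the haplotype mix", {
  # mutant-only coverage confirms; a 50:50 mix never does
  cfg <- sim_config(seed = 79, n_genes = 25, n_species = 3,
                    branch_loss_prob = 0.12, na_rate = 0,
                    assembly_gap_rate = 0, max_read_loci = 8L,
                    ancestral_read_fraction = 0.5)
  dir <- withr::local_tempdir()
  d <- simulate_dataset(cfg, dir)
  expect_false(is.null(d$ledger$loci))
  loci <- read_gene_table(file.path(dir, "validation_loci.tsv"))
  out <- validate_mutations(loci, file.path(dir, "reads", "contigs.fa"),
                            file.path(dir, "reads"))
  expect_true(all(out$status == "UNCONFIRMED"))
  expect_true(all(out$n_ancestral > 0L))
})
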