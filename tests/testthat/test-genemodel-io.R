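# Gene-model construction and ingestion of the standard formats.

test_that("gene_model enforces phases, ordering and frame divisibility", {
  m <- gene_model("G", "G.T1", "chr1", "+",
                  cbind(start = c(100L, 200L), end = c(160L, 260L)))
  expect_equal(m$phase_per_exon, c(0L, 0L))
  expect_equal(m$cds_length, 120L)
  # phases follow cumulative coding length mod 3
  m2 <- gene_model("G", "G.T2", "chr1", "+",
                   cbind(start = c(0L, 100L, 200L),
                         end = c(7L, 108L, 260L)))
  expect_equal(m2$phase_per_exon, c(0L, 1L, 0L))
  # minus strand: transcription order is descending genomic order
  expect_error(gene_model("G", "G.T3", "chr1", "-",
                          cbind(start = c(100L, 200L),
                                end = c(160L, 260L))),
               "transcription order")
  m3 <- gene_model("G", "G.T3", "chr1", "-",
                   cbind(start = c(200L, 100L), end = c(260L, 160L)))
  expect_equal(m3$exons[1L, "start"], c(start = 200L))
  expect_error(gene_model("G", "G.T4", "chr1", "+",
                          cbind(start = 0L, end = 100L)),
               "not divisible by 3")
  expect_error(gene_model("G", "G.T5", "chr1", "+",
                          cbind(start = c(0L, 50L), end = c(60L, 110L))),
               "overlapping")
})

test_that("BED12 coding exons are the thick-trimmed blocks", {
  # blockCount = 3; thick interval trims the first block entirely and the
  # second block partially; hand-computed intersection arithmetic:
  # blocks at [1000,1050) [1100,1160) [1200,1250); thick [1130,1246)
  # -> coding exons [1130,1160) (30 bp) and [1200,1246) (46 bp); 76 bp is
  # not divisible by 3, so widen thick end to 1248 -> 30 + 48 = 78 bp
  bed <- paste("chr7", 1000L, 1250L, "GX|GX.T1|1", 0L, "+",
               1130L, 1248L, "0", 3L, "50,60,50,", "0,100,200,",
               sep = "\t")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed, f)
  models <- read_gene_models(f)
  expect_length(models, 1L)
  m <- models[[1L]]
  expect_equal(unname(m$exons),
               matrix(c(1130L, 1160L, 1200L, 1248L), 2L, byrow = TRUE))
  expect_equal(m$cds_length, 78L)
  expect_true(m$is_principal)
})

test_that("BED12 write/read round-trips models including minus strand", {
  m1 <- toy_model(c(10L, 15L), gene = "GA", tx = "GA.T1")
  m2 <- gene_model("GB", "GB.T1", "chr2", "-",
                   cbind(start = c(500L, 300L), end = c(560L, 390L)),
                   is_principal = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_gene_models_bed(list(m1, m2), f)
  back <- read_gene_models(f)
  expect_length(back, 2L)
  for (k in 1:2) {
    orig <- list(m1, m2)[[k]]
    got <- back[[if (back[[1L]]$gene_id == orig$gene_id) 1L else 2L]]
    expect_equal(got$exons, orig$exons)
    expect_equal(got$strand, orig$strand)
    expect_equal(got$phase_per_exon, orig$phase_per_exon)
    expect_equal(got$is_principal, orig$is_principal)
  }
})

test_that("GTF CDS features are grouped, converted and flagged", {
  gtf <- c(
    'chr1\tsrc\tCDS\t101\t160\t.\t+\t0\tgene_id "g1"; transcript_id "t1"; tag "appris_principal";',
    'chr1\tsrc\tCDS\t201\t260\t.\t+\t0\tgene_id "g1"; transcript_id "t1"; tag "appris_principal";',
    'chr1\tsrc\tCDS\t501\t560\t.\t-\t0\tgene_id "g2"; transcript_id "t2";',
    'chr1\tsrc\tCDS\t401\t460\t.\t-\t0\tgene_id "g2"; transcript_id "t2";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  models <- read_gene_models(f)
  expect_length(models, 2L)
  t1 <- models[[which(vapply(models, `[[`, "", "transcript_id") == "t1")]]
  expect_equal(unname(t1$exons[, "start"]), c(100L, 200L))
  expect_true(t1$is_principal)
  t2 <- models[[which(vapply(models, `[[`, "", "transcript_id") == "t2")]]
  expect_equal(t2$strand, "-")
  # transcription order: genomic-descending for minus strand
  expect_equal(unname(t2$exons[, "start"]), c(500L, 400L))
  expect_false(t2$is_principal)
})

test_that("frame-violating records are skipped with a report", {
  bed <- c(
    paste("chr1", 0L, 100L, "G1|G1.T1|1", 0L, "+", 0L, 100L, "0", 1L,
          "100,", "0,", sep = "\t"),
    paste("chr1", 200L, 260L, "G2|G2.T1|1", 0L, "+", 200L, 260L, "0", 1L,
          "60,", "0,", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed, f)
  expect_warning(models <- read_gene_models(f), "divisible by 3")
  expect_length(models, 1L)
  expect_equal(models[[1L]]$gene_id, "G2")
  skipped <- attr(models, "skipped")
  expect_equal(nrow(skipped), 1L)
  expect_equal(skipped$line, 1L)
})

test_that("exon_sequences respects strand and transcription order", {
  genome <- c(chrT = "aaaaATGGCAgggTTAcccc")
  m_plus <- gene_model("G", "G.Tp", "chrT", "+",
                       cbind(start = c(4L, 13L), end = c(10L, 16L)))
  expect_equal(exon_sequences(m_plus, genome), c("atggca", "tta"))
  m_minus <- gene_model("G", "G.Tm", "chrT", "-",
                        cbind(start = c(13L, 4L), end = c(16L, 10L)))
  expect_equal(exon_sequences(m_minus, genome), c("taa", "tgccat"))
})

test_that("Newick round-trip preserves topology", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
})

test_that("OBO levels follow the shortest is_a path to the root", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: R", "name: root", "",
           "[Term]", "id: t1", "name: one", "is_a: R ! root", "",
           "[Term]", "id: t2", "name: two", "is_a: t1", "",
           "[Term]", "id: a", "name: a", "is_a: R", "",
           "[Term]", "id: b", "name: b", "is_a: R", "",
           "[Term]", "id: c", "name: c", "is_a: a", "is_a: b", "",
           "[Term]", "id: obs", "name: gone", "is_a: c",
           "is_obsolete: true", "")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, f)
  ont <- read_obo(f)
  lv <- setNames(ont$terms$level, ont$terms$id)
  expect_equal(lv[["R"]], 1L)
  expect_equal(lv[["t2"]], 3L)
  # diamond: level(c) = 3 under the shortest-path rule; brute-force agrees
  expect_equal(lv[["c"]], 3L)
  expect_equal(level_oracle(ont, "c"), 3L)
  expect_false("obs" %in% ont$terms$id)
  expect_setequal(term_ancestors(ont, "c"), c("a", "b", "R"))
})

test_that("cyclic or multi-root ontologies are rejected", {
  bad <- c("[Term]", "id: x", "name: x", "is_a: y", "",
           "[Term]", "id: y", "name: y", "is_a: x", "")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(bad, f)
  expect_error(read_obo(f), "cycle|root")
})

test_that("OBO write/read round-trips the synthetic ontology", {
  set.seed(11)
  ont <- build_sim_ontology(n_l2 = 4L, n_l3 = 6L, n_l4 = 10L, n_l5 = 4L)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(ont, f)
  back <- read_obo(f)
  expect_setequal(back$terms$id, ont$terms$id)
  expect_equal(back$terms$level[match(ont$terms$id, back$terms$id)],
               ont$terms$level)
  for (id in ont$terms$id)
    expect_setequal(back$parents[[id]], ont$parents[[id]])
})
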