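# The reading-frame / exon-fraction loss rule.

mut_at <- function(codons, exon = 0L, kind = "PREMATURE_STOP") {
  n <- length(codons)
  data.frame(kind = rep_len(kind, n), exon_index = rep_len(as.integer(exon), n),
             codon_position = as.integer(codons),
             ref_allele = rep_len("x", n), query_allele = rep_len("y", n),
             indel_length = rep_len(NA_integer_, n),
             stringsAsFactors = FALSE)
}

test_that("intact fraction is the larger clean terminal flank", {
  m <- toy_model(100L)                   # 100 codons, single exon
  none <- mut_at(integer(0))
  expect_equal(intact_fraction(m, none), 1)
  # single mutation at codon 51: flanks are 50 and 49 codons
  expect_equal(intact_fraction(m, mut_at(51L)), 0.50)
  # oracle: count both flanks directly
  f <- 51L
  expect_equal(max((f - 1) / 100, (100 - f) / 100), 0.50)
  # both terminal codons hit: nothing intact
  expect_equal(intact_fraction(m, mut_at(c(1L, 100L))), 0)
  # exon deletion contributes the exon's full codon span
  m3 <- toy_model(c(40L, 30L, 30L))
  del <- data.frame(kind = "EXON_DELETED", exon_index = 1L,
                    codon_position = NA_integer_, ref_allele = "+",
                    query_allele = "-", indel_length = NA_integer_)
  # exon 2 spans codons 41-70: flanks 40 and 30
  expect_equal(intact_fraction(m3, del), 0.40)
})

test_that("the max-stretch alternative measures internal gaps too", {
  m <- toy_model(100L)
  muts <- mut_at(c(21L, 80L))
  expect_equal(intact_fraction(m, muts, rule = "terminal_flank"), 0.20)
  # clean stretches: 20, 58, 20 codons
  expect_equal(intact_fraction(m, muts, rule = "max_stretch"), 0.58)
})

test_that("adding mutations never raises the intact fraction", {
  set.seed(21)
  m <- toy_model(c(50L, 50L))
  for (rep in 1:50) {
    cods <- sort(sample(2:99, 5L))
    prev <- 1
    for (k in 1:5) {
      cur <- intact_fraction(m, mut_at(cods[1:k]))
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("loss needs <60% intact AND >=20% of exons hit, as printed", {
  th <- loss_thresholds()
  m <- toy_model(rep(3L, 10L))           # 10 exons x 3 codons, L = 30
  status <- rep("ALIGNED", 10L)
  # 0.55 intact via first mutation at codon 17((17-1)/30 = 0.533), three
  # exons hit -> lost
  muts <- mut_at(c(17L, 20L, 23L), exon = c(5L, 6L, 7L))
  r <- classify_transcript(m, muts, status, th)
  expect_true(r$lost)
  expect_equal(r$exon_fraction_hit, 0.3)
  expect_equal(r$rationale, "FRAME_AND_EXON_RULE")
  # intact fraction exactly 0.60 -> NOT lost (strict inequality)
  m2 <- toy_model(rep(10L, 10L))         # L = 100
  muts2 <- mut_at(c(61L, 65L), exon = c(6L, 6L))
  r2 <- classify_transcript(m2, muts2, status, th)
  expect_equal(r2$intact_fraction, 0.60)
  expect_false(r2$lost)
  # exon fraction below 20% blocks the call even when the frame is gone
  muts3 <- mut_at(c(41L, 45L), exon = c(4L, 4L))
  r3 <- classify_transcript(m2, muts3, status, th)
  expect_lt(r3$intact_fraction, 0.60)
  expect_equal(r3$exon_fraction_hit, 0.1)
  expect_false(r3$lost)
})

test_that("single-exon genes need at least two inactivating mutations", {
  th <- loss_thresholds()
  m <- toy_model(100L)
  status <- "ALIGNED"
  expect_false(classify_transcript(m, mut_at(50L), status, th)$lost)
  r <- classify_transcript(m, mut_at(c(50L, 60L)), status, th)
  expect_true(r$lost)
  expect_equal(r$rationale, "SINGLE_EXON_MULTI_MUTATION")
})

test_that("missing exons leave the exon denominator", {
  th <- loss_thresholds()
  m <- toy_model(rep(10L, 10L))
  status <- c(rep("ALIGNED", 5L), rep("MISSING", 5L))
  # 1 exon of 5 non-missing hit = 20% -> counts; of 10 it would be 10%
  muts <- mut_at(45L, exon = 4L)
  r <- classify_transcript(m, muts, status, th)
  expect_equal(r$exon_fraction_hit, 0.2)
  expect_true(r$lost)
  # everything missing -> no data
  r2 <- classify_transcript(m, mut_at(integer(0)),
                            rep("MISSING", 10L), th)
  expect_true(r2$no_data)
})

test_that("a gene is lost only when all principal isoforms are lost", {
  lostiso <- list(lost = TRUE, no_data = FALSE, intact_fraction = 0.3,
                  exon_fraction_hit = 0.5, n_mutations = 3L,
                  rationale = "FRAME_AND_EXON_RULE")
  okiso <- list(lost = FALSE, no_data = FALSE, intact_fraction = 0.9,
                exon_fraction_hit = 0.1, n_mutations = 1L,
                rationale = "NOT_LOST")
  nodata <- list(lost = NA, no_data = TRUE, intact_fraction = NA_real_,
                 exon_fraction_hit = NA_real_, n_mutations = 0L,
                 rationale = "NO_DATA")
  expect_true(classify_gene(list(lostiso, lostiso))$lost)
  both <- classify_gene(list(lostiso, okiso))
  expect_false(both$lost)
  expect_equal(both$best_intact_fraction, 0.9)
  # isoforms without data do not veto
  expect_true(classify_gene(list(lostiso, nodata))$lost)
  expect_equal(classify_gene(list(nodata))$rationale, "NO_DATA")
})

test_that("the loss matrix is deterministic with NA for no-data calls", {
  calls <- rbind(
    data.frame(gene_id = "g2", species = "s1", lost = TRUE,
               best_intact_fraction = 0.2, exon_fraction_hit = 0.5,
               n_mutations = 2L, rationale = "FRAME_AND_EXON_RULE"),
    data.frame(gene_id = "g1", species = "s2", lost = NA,
               best_intact_fraction = NA, exon_fraction_hit = NA,
               n_mutations = 0L, rationale = "NO_DATA"),
    data.frame(gene_id = "g1", species = "s1", lost = FALSE,
               best_intact_fraction = 1, exon_fraction_hit = 0,
               n_mutations = 0L, rationale = "NOT_LOST"),
    data.frame(gene_id = "g3", species = "s1", lost = FALSE,
               best_intact_fraction = 1, exon_fraction_hit = 0,
               n_mutations = 0L, rationale = "NOT_LOST"))
  mat <- build_loss_matrix(calls)
  expect_equal(rownames(mat), c("g1", "g2", "g3"))
  expect_equal(colnames(mat), c("s1", "s2"))
  expect_equal(sum(mat == "LOST", na.rm = TRUE), 1L)
  expect_true(is.na(mat["g1", "s2"]))
  expect_true(is.na(mat["g2", "s2"]))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_loss_matrix(mat, f)
  expect_equal(read_loss_matrix(f), mat)
})
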