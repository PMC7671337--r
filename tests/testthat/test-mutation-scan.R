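# Detection of the inactivating-mutation classes.

# independent oracle: translate the query CDS codon-by-codon in the
# reference frame and list positions carrying a stop
stop_oracle <- function(ref_exons, q_exons) {
  ref <- paste(ref_exons, collapse = "")
  qry <- paste(q_exons, collapse = "")
  L <- nchar(ref) / 3L
  hits <- integer(0)
  for (c0 in seq_len(L - 1L)) {
    rcod <- substr(ref, 3L * c0 - 2L, 3L * c0)
    qcod <- substr(qry, 3L * c0 - 2L, 3L * c0)
    if (qcod %in% c("taa", "tag", "tga") && qcod != rcod)
      hits <- c(hits, c0)
  }
  hits
}

test_that("premature stops are found in the reference frame", {
  cpe <- c(40L, 35L, 25L)           # 100 codons over 3 exons
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  # unchanged query (terminal taa) -> nothing
  recs <- make_recs(m, ref_exons = seqs)
  expect_equal(nrow(detect_premature_stops(m, recs)), 0L)
  # gaa -> taa at codon 10
  q <- put_codon(seqs, cpe, 10L, "taa")
  stopifnot(substr(seqs[1L], 28L, 30L) != "taa")
  recs <- make_recs(m, q_exons = q, ref_exons = seqs)
  got <- detect_premature_stops(m, recs)
  expect_equal(got$kind, "PREMATURE_STOP")
  expect_equal(got$codon_position, 10L)
  expect_equal(got$exon_index, 0L)
  expect_equal(got$codon_position, stop_oracle(seqs, q))
  # several stops, one crossing into a later exon, all match the oracle
  q2 <- put_codon(q, cpe, 50L, "tga")
  q2 <- put_codon(q2, cpe, 90L, "tag")
  recs2 <- make_recs(m, q_exons = q2, ref_exons = seqs)
  got2 <- detect_premature_stops(m, recs2)
  expect_equal(got2$codon_position, stop_oracle(seqs, q2))
})

test_that("stop codons split by an exon junction are read spliced", {
  # exon 1 ends mid-codon (10 bp), exon 2 carries the rest (11 bp)
  m <- gene_model("G", "G.T1", "chr1", "+",
                  cbind(start = c(0L, 100L), end = c(10L, 111L)))
  ref1 <- "atggcagcag"          # codon 4 = g|ca split across the junction
  ref2 <- "cagcagcttaa"
  # query turns codon 4 (CDS positions 10-12) into tga: base 10 is the
  # last of exon 1, bases 11-12 lead exon 2
  q1 <- "atggcagcat"
  q2 <- "gagcagcttaa"
  recs <- list(
    genelossr:::exon_alignment("G", "G.T1", 0L, "s", "ALIGNED", ref1, q1,
                               query_donor = "gt"),
    genelossr:::exon_alignment("G", "G.T1", 1L, "s", "ALIGNED", ref2, q2,
                               query_acceptor = "ag"))
  got <- detect_premature_stops(m, recs)
  expect_equal(got$codon_position, 4L)
  expect_equal(got$query_allele, "tga")
})

test_that("frameshifts are maximal gap runs of length not divisible by 3", {
  cpe <- c(40L, 40L, 40L, 40L, 40L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  # in-frame 3 bp deletion -> nothing
  q <- seqs
  substr(q[2L], 31L, 33L) <- "---"
  recs <- make_recs(m, q_exons = q, ref_exons = seqs)
  expect_equal(nrow(detect_frameshifts(m, recs)), 0L)
  # 4 bp deletion in exon index 3 (the fourth exon)
  q <- seqs
  substr(q[4L], 13L, 16L) <- "----"
  recs <- make_recs(m, q_exons = q, ref_exons = seqs)
  got <- detect_frameshifts(m, recs)
  expect_equal(got$kind, "FRAMESHIFT_DEL")
  expect_equal(got$exon_index, 3L)
  expect_equal(got$indel_length, 4L)
  # codon of the first deleted base: exon 4 starts at codon 121
  expect_equal(got$codon_position, 121L + 4L)
  # two separate 1 bp and 2 bp deletions 30 bp apart: two events, even
  # though the net frame is restored
  q <- seqs
  substr(q[1L], 10L, 10L) <- "-"
  substr(q[1L], 40L, 41L) <- "--"
  recs <- make_recs(m, q_exons = q, ref_exons = seqs)
  got <- detect_frameshifts(m, recs)
  expect_equal(got$kind, c("FRAMESHIFT_DEL", "FRAMESHIFT_DEL"))
  expect_equal(got$indel_length, c(1L, 2L))
  # oracle: maximal runs enumerated independently via rle
  runs <- rle(chars(q[1L]) == "-")
  expect_equal(sum(runs$values & runs$lengths %% 3L != 0L), 2L)
})

test_that("insertions in the query are reference-side gap runs", {
  cpe <- c(40L, 40L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  ref <- seqs
  q <- seqs
  # 2 bp insertion after base 21 of exon 1 (codon 8)
  ref[1L] <- paste0(substr(ref[1L], 1L, 21L), "--",
                    substr(ref[1L], 22L, 120L))
  q[1L] <- paste0(substr(seqs[1L], 1L, 21L), "ca",
                  substr(seqs[1L], 22L, 120L))
  recs <- make_recs(m, q_exons = q, ref_exons = ref)
  got <- detect_frameshifts(m, recs)
  expect_equal(got$kind, "FRAMESHIFT_INS")
  expect_equal(got$indel_length, 2L)
  expect_equal(got$codon_position, 7L)
  expect_equal(got$query_allele, "ca")
})

test_that("splice-site deviations follow the GT/GC + AG rule", {
  cpe <- c(20L, 20L, 20L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  # enumerate all 16 donor dinucleotides: only gt and gc are intact
  for (d in as.vector(outer(c("a", "c", "g", "t"), c("a", "c", "g", "t"),
                            paste0))) {
    recs <- make_recs(m, ref_exons = seqs, donors = c(d, "gt", NA))
    got <- detect_splice_mutations(m, recs)
    if (d %in% c("gt", "gc")) expect_equal(nrow(got), 0L)
    else {
      expect_equal(got$kind, "SPLICE_DONOR")
      expect_equal(got$exon_index, 0L)
      expect_equal(got$codon_position, 20L)
    }
  }
  # all 16 acceptors: only ag intact
  for (a in as.vector(outer(c("a", "c", "g", "t"), c("a", "c", "g", "t"),
                            paste0))) {
    recs <- make_recs(m, ref_exons = seqs, acceptors = c(NA, "ag", a))
    got <- detect_splice_mutations(m, recs)
    if (a == "ag") expect_equal(nrow(got), 0L)
    else {
      expect_equal(got$kind, "SPLICE_ACCEPTOR")
      expect_equal(got$exon_index, 2L)
      expect_equal(got$codon_position, 41L)
    }
  }
  # N dinucleotides are missing data, not mutations
  recs <- make_recs(m, ref_exons = seqs, donors = c("nn", "gt", NA))
  expect_equal(nrow(detect_splice_mutations(m, recs)), 0L)
  # intact acceptor next to a broken donor: one event only
  recs <- make_recs(m, ref_exons = seqs, donors = c("gg", "gt", NA))
  expect_equal(detect_splice_mutations(m, recs)$kind, "SPLICE_DONOR")
  # single-exon genes have no splice sites
  m1 <- toy_model(100L)
  recs1 <- make_recs(m1, ref_exons = toy_exon_seqs(100L))
  expect_equal(nrow(detect_splice_mutations(m1, recs1)), 0L)
})

test_that("unaligned exons are split into deletions vs assembly gaps", {
  th <- loss_thresholds(min_gap_run = 10L)
  expect_equal(classify_exon_status(NA, th), "MISSING")
  expect_equal(classify_exon_status(strrep("n", 12L), th), "MISSING")
  expect_equal(classify_exon_status(
    paste0("acgt", strrep("N", 10L), "acgt"), th), "MISSING")
  expect_equal(classify_exon_status(strrep("n", 9L), th), "DELETED")
  expect_equal(classify_exon_status("acgtacgtacgt", th), "DELETED")
})

test_that("whole-gene deletion subsumes per-exon deletions", {
  cpe <- c(20L, 20L, 20L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  ctx <- setNames(rep("acgtacgt", 3L),
                  sprintf("%s:%d", m$transcript_id, 0:2))
  # all exons deleted (TYMP-in-tenrec style): a single GENE_DELETED event
  res <- scan_transcript(m, list(), contexts = ctx)
  expect_equal(res$mutations$kind, "GENE_DELETED")
  expect_equal(res$status, rep("DELETED", 3L))
  # one deleted exon among aligned ones: one EXON_DELETED event
  recs <- make_recs(m, ref_exons = seqs, skip = 2L)
  res <- scan_transcript(m, recs, contexts = ctx)
  expect_equal(res$mutations$kind, "EXON_DELETED")
  expect_equal(res$mutations$exon_index, 1L)
  # deleted + missing everywhere: exon deletions reported, no gene event
  ctx2 <- ctx; ctx2[2L] <- strrep("n", 15L)
  res <- scan_transcript(m, list(), contexts = ctx2)
  expect_setequal(res$mutations$kind, "EXON_DELETED")
  expect_equal(nrow(res$mutations), 2L)
})

test_that("UOX-like fixtures reproduce the published mutation pattern", {
  # 5-exon gene; elephant-like species: stop codon in exon 3 (index 2);
  # manatee-like species: 4 bp deletion in exon 4 (index 3) plus a stop
  # codon in exon 5 (index 4)
  cpe <- c(30L, 30L, 30L, 30L, 30L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  q_ele <- put_codon(seqs, cpe, 70L, "tga")      # codon 70 sits in exon 3
  got <- scan_transcript(m, make_recs(m, q_exons = q_ele,
                                      ref_exons = seqs))$mutations
  expect_equal(got$kind, "PREMATURE_STOP")
  expect_equal(got$exon_index, 2L)
  q_man <- put_codon(seqs, cpe, 130L, "taa")     # codon 130 in exon 5
  substr(q_man[4L], 10L, 13L) <- "----"
  got <- scan_transcript(m, make_recs(m, q_exons = q_man,
                                      ref_exons = seqs))$mutations
  expect_equal(got$kind, c("FRAMESHIFT_DEL", "PREMATURE_STOP"))
  expect_equal(got$exon_index, c(3L, 4L))
  expect_equal(got$indel_length, c(4L, NA_integer_))
})

test_that("neutral edits never produce mutations and output is sorted", {
  # property: synonymous substitutions and in-frame indels only
  cfg <- sim_config(seed = 99, n_genes = 25, n_species = 2,
                    branch_loss_prob = 0, convergence_rate = 0,
                    syn_sub_rate = 0.1, inframe_del_rate = 0.2,
                    assembly_gap_rate = 0, na_rate = 0)
  d <- simulate_dataset(cfg)
  for (sp in colnames(d$history$truth)) {
    blocks <- d$alignments$per_species[[sp]]$blocks
    expect_false(identical(blocks$ref_text, blocks$q_text)) # edits present
  }
  expect_null(d$ledger$mutations)
  # and the scanner agrees: no mutations anywhere
  dir <- withr::local_tempdir()
  d <- simulate_dataset(cfg, dir)
  models <- read_gene_models(file.path(dir, "genes.bed"))
  for (maf in list.files(file.path(dir, "aln"), full.names = TRUE)) {
    alns <- read_exon_alignments(maf, models)
    scan <- scan_species(models, alns)
    expect_equal(nrow(scan$mutations), 0L)
  }
})

test_that("scan output order is deterministic", {
  cpe <- c(30L, 30L, 30L)
  m <- toy_model(cpe)
  seqs <- toy_exon_seqs(cpe)
  q <- put_codon(seqs, cpe, 50L, "taa")
  q <- put_codon(q, cpe, 10L, "tga")
  substr(q[3L], 7L, 7L) <- "-"
  recs <- make_recs(m, q_exons = q, ref_exons = seqs,
                    donors = c("tt", "gt", NA))
  r1 <- scan_transcript(m, recs)$mutations
  r2 <- scan_transcript(m, recs)$mutations
  expect_identical(r1, r2)
  expect_equal(r1$exon_index, sort(r1$exon_index))
})
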