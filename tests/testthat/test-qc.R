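test_that("alignment-category fractions are exact and sum to one", {
  log <- matrix(c(6, 1, 1, 1, 1), 1, 5,
                dimnames = list("S1", c("feature", "no_feature", "ambiguous",
                                        "multimapped", "unmapped")))
  bd <- alignment_breakdown(log)
  expect_equal(bd$mapped_to_genes, 0.6)
  expect_equal(bd$no_feature, 0.1)
  expect_equal(bd$mapped_to_genes + bd$no_feature + bd$ambiguous +
                 bd$multimapped + bd$unmapped, 1, tolerance = 1e-9)

  all_un <- matrix(c(0, 0, 0, 0, 7), 1, 5, dimnames = dimnames(log))
  expect_equal(alignment_breakdown(all_un)$unmapped, 1.0)

  # empty sample: fractions 0, no NaN
  zero <- matrix(0, 1, 5, dimnames = dimnames(log))
  expect_equal(alignment_breakdown(zero)$unmapped, 0)
})

test_that("breakdown matches per-record oracle classification on a fixture", {
  ann <- make_toy_annotation(tempfile(fileext = ".gtf"), n_genes = 8, seed = 2)
  gm <- load_gene_model(ann$gtf)
  bs <- default_bs()
  rs <- parse_read_structure("B6N6")
  sim <- simulate_brbseq_library(gm, bs, rs, tempfile(),
                                 mean_molecules = 8, dup_p = 0.6,
                                 frac_unmapped = 0.1, frac_multimapped = 0.1,
                                 frac_intergenic = 0.1, seed = 9)
  res <- count_tagged_alignments(sim$sam, gm, bs, rs, r1 = sim$r1)
  bd <- alignment_breakdown(res$log)
  # tally the simulator's per-read truth independently
  tr <- sim$truth$per_read
  for (s in bs$sample_id) {
    sub <- tr[tr$sample_id == s, ]
    row <- bd[bd$sample_id == s, ]
    # each multimapped read contributes a secondary record as well
    n_mm <- sum(sub$category == "multimapped")
    tot <- nrow(sub) + n_mm
    expect_equal(row$total, tot)
    expect_equal(row$unmapped, sum(sub$category == "unmapped") / tot)
    expect_equal(row$multimapped, 2 * n_mm / tot)
    expect_equal(row$mapped_to_genes, sum(sub$category == "normal") / tot)
    expect_equal(row$no_feature, sum(sub$category == "intergenic") / tot)
  }
})

test_that("MT-rRNA fraction sums the two named genes over the total", {
  cm <- list(genes = c("MT-RNR1", "MT-RNR2", "G1"), samples = c("S1", "S2"),
             reads = matrix(c(6, 4, 90, 0, 0, 50), 3, 2,
                            dimnames = list(c("MT-RNR1", "MT-RNR2", "G1"),
                                            c("S1", "S2"))))
  class(cm) <- "CountMatrices"
  f <- mt_fraction(cm)
  expect_equal(unname(f["S1"]), 0.10)
  expect_equal(unname(f["S2"]), 0)
  # no MT genes in the matrix -> 0, not NA
  cm2 <- cm; cm2$reads <- cm$reads[3, , drop = FALSE]
  expect_equal(unname(mt_fraction(cm2)), c(0, 0))
  # zero-depth sample -> 0
  cm3 <- cm; cm3$reads[, 2] <- 0L
  expect_equal(unname(mt_fraction(cm3)["S2"]), 0)
})

test_that("detected gene counts step down monotonically in the threshold", {
  cm <- list(genes = paste0("g", 1:3), samples = "S1",
             reads = matrix(c(0L, 1L, 6L), 3, 1,
                            dimnames = list(paste0("g", 1:3), "S1")))
  class(cm) <- "CountMatrices"
  d <- detected_genes(cm)
  expect_equal(unname(d[1, ]), c(2L, 1L, 1L, 0L))
  # random matrices stay monotone
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rpois(60, 3), 20, 3,
                dimnames = list(paste0("g", 1:20), paste0("S", 1:3)))
    cmr <- structure(list(genes = rownames(m), samples = colnames(m),
                          reads = m), class = "CountMatrices")
    d <- detected_genes(cmr, thresholds = 0:6)
    expect_true(all(apply(d, 1, diff) <= 0))
    # recompute by filtering
    expect_equal(unname(d[, "reads>2"]), unname(colSums(m > 2)))
  }
})

test_that("UMI duplication is one minus the molecule/read ratio", {
  cm <- structure(list(genes = "g", samples = c("S1", "S2"),
                       reads = matrix(c(10L, 5L), 1, 2),
                       umis = matrix(c(4L, 5L), 1, 2)),
                  class = "CountMatrices")
  expect_equal(unname(umi_duplication(cm)), c(0.6, 0.0))
  cm$reads[] <- 0L; cm$umis[] <- 0L
  expect_equal(unname(umi_duplication(cm)), c(0, 0))
})

test_that("gene-body coverage is flat under uniform coverage and 3' for biased reads", {
  gm <- load_gene_model(write_gtf(gtf_line("chr1", 1, 1000, "+", "A")))
  # tile the gene with overlapping 50-mers, uniform start every base
  pos <- 1:951
  aln <- data.frame(pos = pos, cigar = "50M", category = "feature",
                    gene_id = "A", stringsAsFactors = FALSE)
  cov <- gene_body_coverage(aln, gm, bins = 10)
  expect_equal(cov$n_bases, length(pos) * 50)
  inner <- cov$profile[2:9]
  expect_true(max(inner) - min(inner) < 0.02)
  expect_equal(max(cov$profile), 1)

  # reads only at the 3' terminus
  aln3 <- data.frame(pos = 951, cigar = "50M", category = "feature",
                     gene_id = "A", stringsAsFactors = FALSE)
  cov3 <- gene_body_coverage(aln3, gm, bins = 10)
  expect_equal(which(cov3$profile > 0), 10L)
})

test_that("minus-strand coverage is the exact mirror of the plus profile", {
  gm_p <- load_gene_model(write_gtf(c(gtf_line("chr1", 1, 400, "+", "A"),
                                      gtf_line("chr1", 601, 1200, "+", "A"))))
  gm_m <- load_gene_model(write_gtf(c(gtf_line("chr1", 1, 400, "-", "A"),
                                      gtf_line("chr1", 601, 1200, "-", "A"))))
  set.seed(8)
  pos <- sample(c(1:351, 601:1151), 60)
  aln <- data.frame(pos = pos, cigar = "50M", category = "feature",
                    gene_id = "A", stringsAsFactors = FALSE)
  cp <- gene_body_coverage(aln, gm_p, bins = 20)
  cm <- gene_body_coverage(aln, gm_m, bins = 20)
  expect_equal(cm$raw, rev(cp$raw))
  expect_equal(cp$n_bases, cm$n_bases)
})

test_that("spliced coverage lands in merged-exon coordinates, not genomic span", {
  # exon1 1-100, exon2 901-1000: body length 200; a read in exon2 covers
  # the second half of the body even though it is 90% through the span
  gm <- load_gene_model(write_gtf(c(gtf_line("chr1", 1, 100, "+", "A"),
                                    gtf_line("chr1", 901, 1000, "+", "A"))))
  aln <- data.frame(pos = 901, cigar = "50M", category = "feature",
                    gene_id = "A", stringsAsFactors = FALSE)
  cov <- gene_body_coverage(aln, gm, bins = 4, min_gene_len = 100)
  expect_equal(cov$raw, c(0, 0, 50, 0))
})

test_that("log-count correlation is 1 for self and scale-shifted libraries", {
  set.seed(4)
  m <- matrix(rnbinom(400, mu = 300, size = 2), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("S", 1:4)))
  r <- correlate_log_counts(m, m)
  expect_equal(unname(r$per_sample), rep(1, 4), tolerance = 1e-12)
  expect_true(isSymmetric(unname(r$matrix)))
  r2 <- correlate_log_counts(m, 2L * m)
  expect_true(all(r2$per_sample > 0.999))
  # against a textbook two-pass Pearson on the log scale
  a <- log2(m[, 1] + 1); b <- log2(m[, 2] + 1)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r$matrix["S1", "S2"]), want, tolerance = 1e-12)
})
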