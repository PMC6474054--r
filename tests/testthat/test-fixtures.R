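sim_setup <- function(n_genes = 10, seed = 5) {
  ann <- make_toy_annotation(tempfile(fileext = ".gtf"), n_genes = n_genes,
                             seed = seed)
  list(gm = load_gene_model(ann$gtf), bs = default_bs(),
       rs = parse_read_structure("B6N6V3"))
}

test_that("simulated libraries are internally consistent and seeded", {
  s <- sim_setup()
  d1 <- tempfile(); d2 <- tempfile()
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, d1, mean_molecules = 10,
                                 seed = 3)
  # R1, R2 and SAM agree on read identity
  r1 <- readLines(sim$r1); r2 <- readLines(sim$r2)
  expect_equal(length(r1), length(r2))
  n_reads <- length(r1) / 4
  ids1 <- sub("^@", "", r1[seq(1, length(r1), 4)])
  ids2 <- sub("^@", "", r2[seq(1, length(r2), 4)])
  expect_identical(ids1, ids2)
  sam_q <- sub("\t.*", "",
               grep("^@", readLines(sim$sam), invert = TRUE, value = TRUE))
  expect_setequal(unique(sam_q), ids1)
  expect_equal(n_reads, sim$config$n_reads)
  expect_equal(nrow(sim$truth$per_read), n_reads)

  # byte-identical outputs under the same seed
  sim2 <- simulate_brbseq_library(s$gm, s$bs, s$rs, d2, mean_molecules = 10,
                                  seed = 3)
  expect_identical(readLines(sim$r1), readLines(sim2$r1))
  expect_identical(readLines(sim$r2), readLines(sim2$r2))
  expect_identical(readLines(sim$sam), readLines(sim2$sam))
})

test_that("generated UMIs honor the non-T V segment exhaustively", {
  s <- sim_setup()
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, tempfile(),
                                 mean_molecules = 15, seed = 8)
  umi <- sim$truth$molecules$umi
  expect_true(all(nchar(umi) == 9L))
  v_part <- substr(umi, 7, 9)
  expect_false(any(grepl("T", v_part, fixed = TRUE)))
})

test_that("duplication factor 1 makes UMI counts equal read counts", {
  s <- sim_setup()
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, tempfile(),
                                 mean_molecules = 10, dup_p = 1, seed = 4)
  expect_true(all(sim$truth$molecules$dup == 1L))
  res <- count_tagged_alignments(sim$sam, s$gm, s$bs, s$rs, r1 = sim$r1)
  expect_identical(res$counts$umis, res$counts$reads)
})

test_that("geometric duplication reproduces the truth duplication ratio", {
  s <- sim_setup()
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, tempfile(),
                                 mean_molecules = 40, dup_p = 0.4, seed = 6)
  res <- count_tagged_alignments(sim$sam, s$gm, s$bs, s$rs, r1 = sim$r1)
  dup <- umi_duplication(res$counts)
  tr <- sim$truth
  for (smp in s$bs$sample_id) {
    mol <- tr$molecules[tr$molecules$sample_id == smp &
                          tr$molecules$category == "normal", ]
    want <- 1 - sum(tr$expected_umis[, smp]) / sum(mol$dup)
    expect_equal(unname(dup[smp]), want, tolerance = 1e-12)
  }
})

test_that("one-mismatch barcode errors are recovered with tolerant demux", {
  # barcode set with pairwise Hamming distance >= 3: 1-mismatch reads stay
  # uniquely closest to their true barcode
  bs <- barcode_set(paste0("S", 1:4),
                    c("AAAAAA", "CCCTTT", "GGGCCC", "TTTGGG"))
  ann <- make_toy_annotation(tempfile(fileext = ".gtf"), n_genes = 6, seed = 2)
  gm <- load_gene_model(ann$gtf)
  rs <- parse_read_structure("B6N6")
  sim <- simulate_brbseq_library(gm, bs, rs, tempfile(), mean_molecules = 15,
                                 barcode_mismatch_frac = 1, seed = 12)
  strict <- demultiplex(sim$r1, sim$r2, bs, rs, tempfile())
  expect_equal(sum(strict$per_sample), 0L)
  tolerant <- demultiplex(sim$r1, sim$r2, bs, rs, tempfile(),
                          max_mismatch = 1L)
  truth_tab <- table(factor(sim$truth$per_read$sample_id,
                            levels = bs$sample_id))
  expect_equal(unname(tolerant$per_sample), as.vector(truth_tab))
  expect_equal(tolerant$unassigned, 0L)
})

test_that("special-fraction reads carry the intended SAM categories", {
  s <- sim_setup()
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, tempfile(),
                                 mean_molecules = 30, frac_unmapped = 0.2,
                                 frac_multimapped = 0.2,
                                 frac_intergenic = 0.2, seed = 10)
  res <- count_tagged_alignments(sim$sam, s$gm, s$bs, s$rs, r1 = sim$r1)
  a <- res$assignments
  tr <- sim$truth$per_read
  m <- match(a$qname, tr$qname)
  expect_false(anyNA(m))
  # primary-record categories map 1:1 onto the truth categories
  primary <- !duplicated(a$qname)
  map <- c(normal = "feature", unmapped = "unmapped",
           multimapped = "multimapped", intergenic = "no_feature")
  expect_equal(a$category[primary],
               unname(map[tr$category[m][primary]]))
  # and the count matrices still equal the truth over normal molecules
  expect_identical(res$counts$reads, sim$truth$expected_reads)
  expect_identical(res$counts$umis, sim$truth$expected_umis)
})

test_that("strong 3' bias shows up in the coverage profile", {
  s <- sim_setup(n_genes = 6)
  sim <- simulate_brbseq_library(s$gm, s$bs, s$rs, tempfile(),
                                 mean_molecules = 60, bias_decay = 30,
                                 seed = 14)
  aln <- assign_reads(read_alignments(sim$sam), s$gm, "forward")
  cov <- gene_body_coverage(aln, s$gm, bins = 10)
  # mass concentrated in the 3'-most bins
  expect_gt(sum(cov$raw[8:10]), sum(cov$raw[1:5]))
  expect_equal(which.max(cov$raw), 10L)
})
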