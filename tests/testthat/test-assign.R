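two_gene_model <- function() {
  load_gene_model(write_gtf(c(
    gtf_line("chr1", 1001, 2000, "+", "A"),
    gtf_line("chr1", 3001, 3500, "+", "A"),   # A has an intron 2001-3000
    gtf_line("chr1", 1800, 2600, "+", "B"),   # overlaps A's first exon
    gtf_line("chr1", 5001, 6000, "-", "C"),
    gtf_line("chr2", 101, 700, "+", "D"))))
}

test_that("basic alignment categories are classified per the union rule", {
  gm <- two_gene_model()
  sam <- write_sam(c(
    sam_record("in_A", 0, "chr1", 1100, "50M"),
    sam_record("amb_AB", 0, "chr1", 1850, "50M"),
    sam_record("in_C_minus", 16, "chr1", 5100, "50M"),
    sam_record("wrong_strand", 16, "chr1", 1100, "50M"),
    sam_record("nofeat", 0, "chr1", 9000, "50M"),
    sam_record("multi", 0, "chr1", 1100, "50M", nh = 2),
    sam_record("second", 256, "chr1", 1100, "50M"),
    sam_record("unmap", 4, "*", 0, "*")))
  aln <- assign_reads(read_alignments(sam), gm, "forward")
  got <- setNames(aln$category, aln$qname)
  expect_equal(unname(got["in_A"]), "feature")
  expect_equal(aln$gene_id[aln$qname == "in_A"], "A")
  expect_equal(unname(got["amb_AB"]), "ambiguous")
  expect_equal(unname(got["in_C_minus"]), "feature")
  expect_equal(unname(got["wrong_strand"]), "no_feature")
  expect_equal(unname(got["nofeat"]), "no_feature")
  expect_equal(unname(got["multi"]), "multimapped")
  expect_equal(unname(got["second"]), "multimapped")
  expect_equal(unname(got["unmap"]), "unmapped")
})

test_that("strand modes invert or drop the compatibility requirement", {
  gm <- two_gene_model()
  sam <- write_sam(sam_record("r", 16, "chr1", 5100, "50M"))  # minus read on C(-)
  for (mode in c("forward", "reverse", "unstranded")) {
    aln <- assign_reads(read_alignments(sam), gm, mode)
    expect_equal(aln$category,
                 if (mode == "reverse") "no_feature" else "feature",
                 info = mode)
  }
  sam2 <- write_sam(sam_record("r", 0, "chr1", 5100, "50M"))  # plus read on C(-)
  aln2 <- assign_reads(read_alignments(sam2), gm, "reverse")
  expect_equal(aln2$gene_id, "C")
})

test_that("spliced reads assign via their aligned blocks only", {
  gm <- two_gene_model()
  # both blocks inside A's two exons, skipping the intron
  sam <- write_sam(sam_record("spl", 0, "chr1", 1981, "20M1000N20M"))
  aln <- assign_reads(read_alignments(sam), gm, "forward")
  expect_equal(aln$category, "ambiguous")  # first block also overlaps B

  sam2 <- write_sam(sam_record("spl2", 0, "chr1", 1700, "20M1281N20M"))
  # blocks 1700-1719 (A+B) ... actually 1700 < 1800 so A only; second block
  # 3001-3020 inside A's second exon
  aln2 <- assign_reads(read_alignments(sam2), gm, "forward")
  expect_equal(aln2$category, "feature")
  expect_equal(aln2$gene_id, "A")

  # a block landing inside A's intron (past B's end) is no_feature
  sam3 <- write_sam(sam_record("intron", 0, "chr1", 2700, "50M"))
  aln3 <- assign_reads(read_alignments(sam3), gm, "forward")
  expect_equal(aln3$category, "no_feature")
})

test_that("reads on chromosomes absent from the model become no_feature", {
  gm <- two_gene_model()
  sam <- write_sam(sam_record("r", 0, "chrX", 100, "50M"),
                   seqlens = c(chrX = 10000L))
  expect_message(aln <- assign_reads(read_alignments(sam), gm, "forward"),
                 "chrX")
  expect_equal(aln$category, "no_feature")
})

test_that("assignment agrees with an exhaustive interval-overlap oracle", {
  set.seed(21)
  for (trial in 1:12) {
    n_genes <- sample(2:5, 1)
    chroms <- c("chr1", "chr2")[seq_len(sample(1:2, 1))]
    glines <- character()
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), stringsAsFactors = FALSE)
    genes$exons <- list()
    exlist <- list()
    for (g in seq_len(n_genes)) {
      gid <- paste0("g", g)
      chr <- sample(chroms, 1)
      strand <- sample(c("+", "-"), 1)
      nex <- sample(1:2, 1)
      pos <- sample(1:3000, 1)
      ex <- matrix(0L, nex, 2)
      for (e in seq_len(nex)) {
        w <- sample(50:300, 1)
        ex[e, ] <- c(pos, pos + w - 1L)
        glines <- c(glines, gtf_line(chr, pos, pos + w - 1L, strand, gid))
        pos <- pos + w + sample(50:400, 1)
      }
      genes <- rbind(genes[, c("gene_id", "chrom", "strand")],
                     data.frame(gene_id = gid, chrom = chr, strand = strand))
      exlist[[gid]] <- ex
    }
    genes$exons <- exlist[genes$gene_id]
    gm <- load_gene_model(write_gtf(glines))

    # random reads, some spliced
    recs <- character()
    truth <- list()
    for (r in 1:15) {
      chr <- sample(chroms, 1)
      rstrand <- sample(c("+", "-"), 1)
      pos <- sample(1:4000, 1)
      spliced <- runif(1) < 0.3
      cigar <- if (spliced) {
        gap <- sample(100:500, 1)
        sprintf("%dM%dN%dM", 20L, gap, 20L)
      } else "40M"
      blocks <- if (spliced) {
        gap <- as.integer(sub("^20M([0-9]+)N20M$", "\\1", cigar))
        rbind(c(pos, pos + 19L), c(pos + 20L + gap, pos + 39L + gap))
      } else rbind(c(pos, pos + 39L))
      recs <- c(recs, sam_record(paste0("r", r),
                                 if (rstrand == "-") 16L else 0L,
                                 chr, pos, cigar))
      truth[[r]] <- list(chrom = chr, strand = rstrand, blocks = blocks)
    }
    sam <- write_sam(recs, seqlens = c(chr1 = 50000L, chr2 = 50000L))
    for (mode in c("forward", "reverse", "unstranded")) {
      aln <- assign_reads(read_alignments(sam), gm, mode)
      for (r in seq_along(truth)) {
        want <- oracle_assign(truth[[r]]$chrom, truth[[r]]$strand,
                              truth[[r]]$blocks, genes, mode)
        i <- which(aln$qname == paste0("r", r))
        expect_equal(aln$category[i], want$category,
                     info = paste("trial", trial, "read", r, mode))
        if (want$category == "feature") {
          expect_equal(aln$gene_id[i], want$gene_id)
        }
      }
    }
  }
})
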