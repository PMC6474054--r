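#' Read alignment records from a SAM or BAM file
#'
#' Thin wrapper over `Rsamtools::scanBam()` that accepts plain-text SAM
#' (converted on the fly) or BAM, and returns the fields needed for gene
#' assignment: query name, flag, chromosome, 1-based position, CIGAR and the
#' NH (number of reported alignments) tag.
#'
#' @param path SAM or BAM file (extension decides).
#' @return A data.frame with columns `qname`, `flag`, `chrom`, `pos`,
#'   `cigar`, `nh` (NA when the tag is absent). One row per alignment record,
#'   including unmapped records.
#'
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag BamFile
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NH"
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$qname))
  data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    nh = nh,
    stringsAsFactors = FALSE
  )
}

#' Assign aligned reads to genes (union mode, strand aware)
#'
#' Classifies every alignment record into one of five categories, following
#' the union-mode convention of htseq-count:
#' * `unmapped` — unmapped flag set;
#' * `multimapped` — secondary/supplementary flag, or NH tag > 1;
#' * `no_feature` — no gene's merged exons overlap any aligned block;
#' * `ambiguous` — the union of genes overlapped by the aligned blocks
#'   contains more than one gene;
#' * `feature` — exactly one gene, reported in `gene_id`.
#'
#' Aligned blocks are the reference ranges consumed by CIGAR M/=/X (and D)
#' operations; N operations split blocks so spliced reads only count where
#' they actually align. Strand compatibility: `forward` requires the read
#' strand to equal the gene strand (3' tag protocols sequence the mRNA
#' sense), `reverse` the opposite, `unstranded` ignores strand. Reads on
#' chromosomes absent from the model are `no_feature` (reported once per
#' chromosome via `message()`).
#'
#' @param aln data.frame from [read_alignments()].
#' @param gm A [load_gene_model()] result.
#' @param strand_mode One of `"forward"` (default), `"reverse"`,
#'   `"unstranded"`.
#'
#' @return `aln` with added columns `category` and `gene_id` (NA unless
#'   `category == "feature"`).
#'
#' @importFrom GenomicAlignments extractAlignmentRangesOnReference
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits elementNROWS
#' @export
assign_reads <- function(aln, gm, strand_mode = c("forward", "reverse",
                                                  "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(gm, "GeneModel"))
  n <- nrow(aln)
  category <- rep("no_feature", n)
  gene_id <- rep(NA_character_, n)

  unmapped <- bitwAnd(aln$flag, 4L) > 0L
  secondary <- bitwAnd(aln$flag, 256L) > 0L | bitwAnd(aln$flag, 2048L) > 0L
  multi <- !unmapped & (secondary | (!is.na(aln$nh) & aln$nh > 1L))
  category[unmapped] <- "unmapped"
  category[multi] <- "multimapped"

  cand <- which(!unmapped & !multi)
  if (length(cand)) {
    known <- aln$chrom[cand] %in% as.character(
      unique(GenomicRanges::seqnames(unlist(gm$exons, use.names = FALSE))))
    if (any(!known)) {
      for (chr in unique(aln$chrom[cand][!known])) {
        message("chromosome '", chr, "' absent from gene model; ",
                "its reads are counted as no_feature")
      }
    }
    cand <- cand[known]
  }
  if (length(cand)) {
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      aln$cigar[cand], aln$pos[cand])
    nb <- S4Vectors::elementNROWS(blocks)
    ridx <- rep(cand, nb)
    read_strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
    bstrand <- read_strand[ridx]
    if (strand_mode == "reverse") {
      bstrand <- ifelse(bstrand == "+", "-", "+")
    }
    bgr <- GenomicRanges::GRanges(
      seqnames = aln$chrom[ridx],
      ranges = unlist(blocks, use.names = FALSE),
      strand = bstrand
    )
    ex <- unlist(gm$exons, use.names = FALSE)
    ex_gene <- rep(names(gm$exons), S4Vectors::elementNROWS(gm$exons))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      bgr, ex, ignore.strand = (strand_mode == "unstranded")))
    if (length(hits)) {
      pair <- unique(data.frame(
        r = ridx[S4Vectors::queryHits(hits)],
        g = ex_gene[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE))
      ngene <- table(pair$r)
      single <- as.integer(names(ngene)[ngene == 1L])
      multi_gene <- as.integer(names(ngene)[ngene > 1L])
      category[multi_gene] <- "ambiguous"
      category[single] <- "feature"
      g1 <- pair[pair$r %in% single, ]
      gene_id[g1$r] <- g1$g
    }
  }
  aln$category <- category
  aln$gene_id <- gene_id
  aln
}
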