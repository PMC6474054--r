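#' Per-sample alignment-category breakdown
#'
#' Fractions of reads per sample that are assigned to a gene, overlap no
#' feature, are ambiguous, multimapped, or unmapped — the standard five-way
#' split used to compare library protocols. The five fractions sum to 1 for
#' every sample with at least one read.
#'
#' @param log A samples x categories count matrix, as produced in the `log`
#'   element of [count_tagged_alignments()], or any matrix with columns
#'   `feature`, `no_feature`, `ambiguous`, `multimapped`, `unmapped`.
#'
#' @return A data.frame, one row per sample, with the five fractions (named
#'   `mapped_to_genes`, `no_feature`, `ambiguous`, `multimapped`,
#'   `unmapped`) and `total` reads.
#' @export
alignment_breakdown <- function(log) {
  cats <- c("feature", "no_feature", "ambiguous", "multimapped", "unmapped")
  stopifnot(all(cats %in% colnames(log)))
  tot <- rowSums(log[, cats, drop = FALSE])
  frac <- log[, cats, drop = FALSE] / ifelse(tot == 0, 1, tot)
  out <- data.frame(sample_id = rownames(log),
                    mapped_to_genes = frac[, "feature"],
                    no_feature = frac[, "no_feature"],
                    ambiguous = frac[, "ambiguous"],
                    multimapped = frac[, "multimapped"],
                    unmapped = frac[, "unmapped"],
                    total = as.integer(tot),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mitochondrial rRNA contamination fraction
#'
#' Mitochondrial contamination is assessed on the two mitochondrial rRNA
#' genes that dominate any mitochondrial signal, MT-RNR1 and MT-RNR2, as the
#' fraction of counts falling on them. The gene list is configurable; genes
#' are matched by `gene_name` when the model provides names, else by
#' `gene_id`.
#'
#' @param cm A `CountMatrices`.
#' @param gm Optional [load_gene_model()] supplying `gene_name`s; when
#'   `NULL`, `mt_genes` are matched against the matrix rownames directly.
#' @param mt_genes Character vector of gene names (default
#'   `c("MT-RNR1", "MT-RNR2")`).
#' @param which `"reads"` (default) or `"umis"`.
#'
#' @return Named numeric vector of per-sample fractions in `[0, 1]`; 0 for a
#'   sample with no counts.
#' @export
mt_fraction <- function(cm, gm = NULL, mt_genes = c("MT-RNR1", "MT-RNR2"),
                        which = "reads") {
  m <- cm[[which]]
  ids <- if (!is.null(gm)) {
    gm$genes$gene_id[gm$genes$gene_name %in% mt_genes |
                       gm$genes$gene_id %in% mt_genes]
  } else {
    intersect(mt_genes, rownames(m))
  }
  tot <- colSums(m)
  mt <- if (length(ids)) colSums(m[rownames(m) %in% ids, , drop = FALSE])
        else rep(0, ncol(m))
  out <- ifelse(tot == 0, 0, mt / tot)
  names(out) <- cm$samples
  out
}

#' Number of detected genes per sample at count thresholds
#'
#' A gene is "detected" at threshold t when its count strictly exceeds t
#' (so `t = 0` means covered by at least one read). Counts are
#' non-increasing in the threshold.
#'
#' @param cm A `CountMatrices`.
#' @param thresholds Integer vector (default `c(0, 1, 5, 10)`).
#' @param which `"reads"` (default) or `"umis"`.
#'
#' @return Integer matrix, samples x thresholds (column names `reads>t`).
#' @export
detected_genes <- function(cm, thresholds = c(0L, 1L, 5L, 10L),
                           which = "reads") {
  m <- cm[[which]]
  out <- vapply(thresholds, function(t) colSums(m > t), numeric(ncol(m)))
  out <- matrix(as.integer(out), ncol(m), length(thresholds))
  dimnames(out) <- list(cm$samples, paste0(which, ">", thresholds))
  out
}

#' UMI-based duplication fraction per sample
#'
#' The UMI gives an unbiased estimate of the PCR/optical duplication rate:
#' `1 - sum(umis) / sum(reads)` per sample (0 when a sample has no reads).
#'
#' @param cm A `CountMatrices`.
#' @return Named numeric vector of per-sample duplication fractions.
#' @export
umi_duplication <- function(cm) {
  r <- colSums(cm$reads)
  u <- colSums(cm$umis)
  out <- ifelse(r == 0, 0, 1 - u / r)
  names(out) <- cm$samples
  out
}

#' Gene-body coverage profile
#'
#' Distribution of aligned bases along the normalized 5'-to-3' merged-exon
#' body of genes, the standard diagnostic for 3' bias. Every
#' feature-assigned primary alignment contributes its aligned block bases,
#' mapped into spliced (merged-exon) coordinates of its gene, oriented
#' 5'-to-3' (reversed for minus-strand genes), scaled to `[0, 1)` by the
#' gene's exonic length, and accumulated into `bins`. The summed profile is
#' scaled so its maximum bin equals 1 (`raw` carries the unscaled base
#' tallies; an all-zero profile stays zero).
#'
#' @param aln Assigned alignments (output of [assign_reads()], or the
#'   `assignments` element of [count_tagged_alignments()] joined back to
#'   blocks — pass the data.frame that still has `pos`/`cigar` columns).
#' @param gm A [load_gene_model()].
#' @param bins Number of bins (default 100).
#' @param min_gene_len Genes with exonic length below this are excluded
#'   (default 100).
#'
#' @return List with `profile` (numeric, max = 1), `raw` (aligned-base count
#'   per bin) and `n_bases` (total aligned bases used).
#'
#' @importFrom GenomicAlignments extractAlignmentRangesOnReference
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors elementNROWS
#' @export
gene_body_coverage <- function(aln, gm, bins = 100L, min_gene_len = 100L) {
  stopifnot(all(c("pos", "cigar", "category", "gene_id") %in% colnames(aln)))
  raw <- numeric(bins)
  use <- which(aln$category == "feature" &
                 gm$genes$exonic_len[match(aln$gene_id,
                                           gm$genes$gene_id)] >= min_gene_len)
  if (length(use)) {
    glen <- stats::setNames(gm$genes$exonic_len, gm$genes$gene_id)
    gstrand <- stats::setNames(gm$genes$strand, gm$genes$gene_id)
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      aln$cigar[use], aln$pos[use])
    nb <- S4Vectors::elementNROWS(blocks)
    bidx <- rep(use, nb)
    bir <- unlist(blocks, use.names = FALSE)
    bgene <- aln$gene_id[bidx]
    # spliced-coordinate offsets per gene: cumulative widths of merged exons
    for (g in unique(bgene)) {
      ex <- gm$exons[[g]]
      exs <- IRanges::start(ex)
      exe <- IRanges::end(ex)
      offs <- cumsum(c(0L, IRanges::width(ex)))[seq_along(exs)]
      sel <- which(bgene == g)
      bs <- IRanges::start(bir)[sel]
      be <- IRanges::end(bir)[sel]
      L <- glen[[g]]
      for (e in seq_along(exs)) {
        s0 <- pmax(bs, exs[e])
        e0 <- pmin(be, exe[e])
        ok <- which(s0 <= e0)
        if (!length(ok)) next
        # spliced 0-based positions of the overlapped stretch
        sp_start <- offs[e] + (s0[ok] - exs[e])
        w <- e0[ok] - s0[ok] + 1L
        pos <- sequence(w, from = sp_start)   # 0-based within body, 5'->3' on +
        if (gstrand[[g]] == "-") pos <- L - 1L - pos
        bin <- pmin(floor(pos * bins / L), bins - 1L) + 1L
        raw <- raw + tabulate(bin, nbins = bins)
      }
    }
  }
  profile <- if (max(raw) > 0) raw / max(raw) else raw
  list(profile = profile, raw = raw, n_bases = sum(raw))
}

#' Pearson correlation of log2 counts between libraries
#'
#' Computes Pearson's r on `log2(count + pseudocount)` over the intersection
#' of gene ids, both per shared sample and as the full cross-sample
#' correlation matrix — the standard technical-replicate concordance metric.
#'
#' @param cm_a,cm_b `CountMatrices` (or plain matrices with gene rownames).
#' @param pseudocount Added before the log (default 1).
#' @param which `"reads"` (default) or `"umis"`.
#'
#' @return List with `per_sample` (named vector over shared sample names)
#'   and `matrix` (samples of `cm_a` x samples of `cm_b`).
#' @export
correlate_log_counts <- function(cm_a, cm_b, pseudocount = 1,
                                 which = "reads") {
  ma <- if (inherits(cm_a, "CountMatrices")) cm_a[[which]] else cm_a
  mb <- if (inherits(cm_b, "CountMatrices")) cm_b[[which]] else cm_b
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 2L) stop("fewer than 2 shared genes")
  la <- log2(ma[shared, , drop = FALSE] + pseudocount)
  lb <- log2(mb[shared, , drop = FALSE] + pseudocount)
  full <- stats::cor(la, lb)
  common <- intersect(colnames(ma), colnames(mb))
  per <- stats::setNames(vapply(common, function(s) full[s, s], numeric(1)),
                         common)
  list(per_sample = per, matrix = full)
}
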