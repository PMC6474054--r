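# Shared fixture builders and independent brute-force oracles.

gtf_line <- function(chr, start, end, strand, gid, gname = gid) {
  sprintf(paste0("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t",
                 "gene_id \"%s\"; transcript_id \"%s.t\"; gene_name \"%s\";"),
          chr, start, end, strand, gid, gid, gname)
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

# One SAM line; seq/qual sized to the CIGAR's read length.
sam_record <- function(qname, flag = 0L, chr = "chr1", pos = 1L,
                       cigar = "50M", nh = 1L) {
  rl <- if (cigar == "*") 10L else {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1]]
    sum(as.integer(sub("[MIS=X]", "", ops)))
  }
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
          qname, flag, chr, pos, if (bitwAnd(flag, 4L)) 0L else 255L,
          cigar, strrep("A", rl), strrep("I", rl), nh)
}

write_sam <- function(records, seqlens = c(chr1 = 100000L, chr2 = 100000L),
                      path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens),
               records), path)
  path
}

write_fastq <- function(names, seqs, path = tempfile(fileext = ".fastq")) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+", qual)), path)
  path
}

default_bs <- function() {
  barcode_set(paste0("S", 1:4), c("AACCGG", "CCGGTT", "GGTTAA", "TTAACC"))
}

# --- brute-force oracles ----------------------------------------------------

# Minimum-Hamming barcode search, one observation at a time.
oracle_match_barcode <- function(obs, barcodes, max_mismatch) {
  oc <- strsplit(obs, "")[[1]]
  d <- vapply(barcodes, function(b) {
    sum(oc != strsplit(b, "")[[1]])
  }, numeric(1))
  best <- min(d)
  if (best > max_mismatch) return(list(id = NA, reason = "no_match"))
  if (sum(d == best) > 1L) return(list(id = NA, reason = "ambiguous"))
  list(id = names(barcodes)[which.min(d)], reason = "ok")
}

# Gene assignment by exhaustive interval overlap. `genes` is a data.frame
# with gene_id, chrom, strand and a list-column `exons` of (start, end)
# 1-based closed matrices.
oracle_assign <- function(chrom, read_strand, blocks, genes, strand_mode) {
  hit <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    if (strand_mode == "forward" && genes$strand[i] != read_strand) next
    if (strand_mode == "reverse" && genes$strand[i] == read_strand) next
    ex <- genes$exons[[i]]
    for (b in seq_len(nrow(blocks))) {
      for (e in seq_len(nrow(ex))) {
        if (blocks[b, 1] <= ex[e, 2] && blocks[b, 2] >= ex[e, 1]) {
          hit <- c(hit, genes$gene_id[i])
        }
      }
    }
  }
  hit <- unique(hit)
  if (length(hit) == 0L) list(category = "no_feature", gene_id = NA)
  else if (length(hit) > 1L) list(category = "ambiguous", gene_id = NA)
  else list(category = "feature", gene_id = hit)
}

# ROC/PR by explicit enumeration of every p-value cutoff.
oracle_roc_pr <- function(pvals, is_pos) {
  cuts <- sort(unique(pvals))
  P <- sum(is_pos)
  N <- sum(!is_pos)
  pts <- t(vapply(cuts, function(t) {
    called <- pvals <= t
    tp <- sum(called & is_pos)
    fp <- sum(called & !is_pos)
    c(fpr = fp / N, tpr = tp / P, prec = tp / (tp + fp))
  }, numeric(3)))
  fpr <- c(0, pts[, "fpr"])
  tpr <- c(0, pts[, "tpr"])
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(roc_auc = trap(fpr, tpr),
       pr_auc = trap(c(0, pts[, "tpr"]), c(pts[1, "prec"], pts[, "prec"])),
       roc = cbind(fpr = fpr, tpr = tpr))
}
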