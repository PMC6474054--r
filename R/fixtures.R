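## Synthetic-library generator: toy annotation and fully specified
## barcoded/UMI-tagged reads with aligned records and ground truth, so the
## demultiplex -> assign -> count pipeline is testable end to end without any
## external data.

#' Generate a toy GTF annotation
#'
#' Lays out non-overlapping multi-exon genes sequentially along `n_chroms`
#' chromosomes, with random strands and exon/intron sizes, and writes a
#' standard GTF. Optionally adds the two mitochondrial rRNA genes
#' (`MT-RNR1`, `MT-RNR2`) on a contig named `MT` so mitochondrial-fraction
#' QC can be exercised.
#'
#' @param gtf Output GTF path.
#' @param n_genes Number of (non-MT) genes.
#' @param n_chroms Number of chromosomes (named `chr1`, ...).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len,gap Integer ranges for exon widths, intron
#'   widths, and intergenic gaps.
#' @param include_mt Add the MT contig with the two rRNA genes.
#' @param seed Integer seed; the output is byte-identical under one seed.
#'
#' @return List with `gtf` (the path), `genes` (data.frame of gene_id,
#'   gene_name, chrom, strand), and `seqlengths` (named vector; each
#'   chromosome extends 20 kb past its last gene, leaving a guaranteed
#'   intergenic zone).
#'
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
make_toy_annotation <- function(gtf, n_genes = 20L, n_chroms = 2L,
                                exons_per_gene = c(1L, 3L),
                                exon_len = c(100L, 300L),
                                intron_len = c(50L, 500L),
                                gap = c(200L, 1000L),
                                include_mt = FALSE, seed = 1L) {
  with_local_seed(seed, {
    runi <- function(rng, n = 1L) {
      if (rng[1] == rng[2]) rep(rng[1], n)
      else sample(seq(rng[1], rng[2]), n, replace = TRUE)
    }
    chroms <- paste0("chr", seq_len(n_chroms))
    cursor <- stats::setNames(rep(1L, n_chroms), chroms)
    rows <- list()
    gene_tab <- list()
    for (i in seq_len(n_genes)) {
      gid <- sprintf("GENE%04d", i)
      chr <- chroms[((i - 1L) %% n_chroms) + 1L]
      strand <- sample(c("+", "-"), 1L)
      nex <- runi(exons_per_gene)
      pos <- cursor[[chr]] + runi(gap)
      for (e in seq_len(nex)) {
        w <- runi(exon_len)
        rows[[length(rows) + 1L]] <- list(chr = chr, start = pos,
                                          end = pos + w - 1L,
                                          strand = strand, gid = gid,
                                          gname = gid, exon = e)
        pos <- pos + w + runi(intron_len)
      }
      cursor[[chr]] <- rows[[length(rows)]]$end
      gene_tab[[i]] <- list(gene_id = gid, gene_name = gid, chrom = chr,
                            strand = strand)
    }
    if (include_mt) {
      pos <- 1000L
      for (nm in c("MT-RNR1", "MT-RNR2")) {
        w <- runi(exon_len)
        rows[[length(rows) + 1L]] <- list(chr = "MT", start = pos,
                                          end = pos + w - 1L, strand = "+",
                                          gid = nm, gname = nm, exon = 1L)
        gene_tab[[length(gene_tab) + 1L]] <-
          list(gene_id = nm, gene_name = nm, chrom = "MT", strand = "+")
        pos <- pos + w + 500L
      }
      cursor <- c(cursor, MT = pos)
      chroms <- c(chroms, "MT")
    }
    df <- do.call(rbind, lapply(rows, as.data.frame))
    attr_col <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; exon_number "%d";',
      df$gid, df$gid, df$gname, df$exon)
    lines <- sprintf("%s\ttoygen\texon\t%d\t%d\t.\t%s\t.\t%s",
                     df$chr, df$start, df$end, df$strand, attr_col)
    atomic_write_lines(c("##gff-version 2", lines), gtf)
    list(gtf = gtf,
         genes = do.call(rbind, lapply(gene_tab, as.data.frame)),
         seqlengths = cursor + 20000L)
  })
}

# Random DNA string(s) of the given length(s).
random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  vapply(len, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a barcoded 3' tag sequencing run with ground truth
#'
#' Emulates the early-multiplexed library construct: per molecule, a UMI is
#' drawn (the N segment uniform over ACGT, the V segment uniform over ACG —
#' never T, as it precedes the oligo-dT), a cDNA fragment start is drawn
#' from an exponential 3'-bias distribution over the merged-exon body, and a
#' PCR duplication factor `1 + Geometric(dup_p)` determines how many reads
#' the molecule yields. Read 1 is barcode + UMI; read 2 is the
#' transcript-derived fragment with optional per-base sequencing errors.
#' Aligned records (SAM) carry the correct chromosome, position and CIGAR
#' (with N operations across introns); designated fractions of molecules
#' are instead emitted as unmapped, multimapped (NH=2 plus a decoy
#' secondary record) or intergenic. Transcript sequence is synthetic random
#' DNA — alignment positions, not homology, define the truth.
#'
#' @param gm A [load_gene_model()] (e.g. from [make_toy_annotation()]).
#' @param bs A [barcode_set()].
#' @param rs A [parse_read_structure()].
#' @param outdir Output directory for `R1.fastq`, `R2.fastq`,
#'   `alignments.sam`, truth tables and the config echo.
#' @param molecules Optional genes x samples integer matrix of true molecule
#'   counts; when `NULL`, drawn NB(`mean_molecules`, dispersion
#'   `mol_dispersion`) per cell.
#' @param mean_molecules,mol_dispersion NB parameters of the molecule draw.
#' @param dup_p Geometric parameter of the duplication factor; `dup_p = 1`
#'   means factor 1 always (UMI count equals read count).
#' @param error_rate Per-base substitution error rate on read 2, in `[0, 1)`.
#' @param frac_unmapped,frac_multimapped,frac_intergenic Fractions of
#'   molecules emitted in each special category (must sum to < 1).
#' @param barcode_mismatch_frac Fraction of reads whose read-1 barcode gets
#'   exactly one substitution error (default 0), for exercising
#'   mismatch-tolerant demultiplexing.
#' @param bias_decay Mean (nt) of the exponential distance of the fragment
#'   start from the 3' end; smaller = stronger 3' bias.
#' @param read_len Read-2 length (fragments are truncated to the transcript).
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#'
#' @return A list of class `SimLibrary`: file paths (`r1`, `r2`, `sam`,
#'   `gtf_truth` etc.), and `truth` containing `molecules` (per-molecule
#'   table), `expected_reads` / `expected_umis` (genes x samples matrices
#'   over normal molecules), `per_read` (intended assignment of every read),
#'   and `config`.
#'
#' @importFrom Biostrings DNAStringSet reverseComplement
#' @importFrom IRanges start end width
#' @export
simulate_brbseq_library <- function(gm, bs, rs, outdir,
                                    molecules = NULL,
                                    mean_molecules = 60, mol_dispersion = 0.3,
                                    dup_p = 0.5, error_rate = 0,
                                    frac_unmapped = 0, frac_multimapped = 0,
                                    frac_intergenic = 0,
                                    barcode_mismatch_frac = 0,
                                    bias_decay = 200, read_len = 50L,
                                    seed = 1L) {
  stopifnot(inherits(gm, "GeneModel"), inherits(bs, "BarcodeSet"),
            inherits(rs, "ReadStructure"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  special <- c(frac_unmapped, frac_multimapped, frac_intergenic)
  if (any(special < 0) || sum(special) > 1) {
    stop("special-read fractions must be >= 0 and sum to <= 1")
  }
  genes <- gm$genes$gene_id
  samples <- bs$sample_id
  if (!is.null(molecules)) {
    if (!all(rownames(molecules) %in% genes)) {
      stop("molecule matrix references unknown gene(s)")
    }
    if (!all(colnames(molecules) %in% samples)) {
      stop("molecule matrix references unknown sample(s)")
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  with_local_seed(seed, {
    G <- length(genes)
    S <- length(samples)
    if (is.null(molecules)) {
      molecules <- matrix(
        stats::rnbinom(G * S, mu = mean_molecules, size = 1 / mol_dispersion),
        G, S, dimnames = list(genes, samples))
    } else {
      full <- matrix(0L, G, S, dimnames = list(genes, samples))
      full[rownames(molecules), colnames(molecules)] <- as.matrix(molecules)
      molecules <- full
    }

    # per-gene synthetic transcript sequence (5'->3', merged-exon body)
    glen <- as.integer(gm$genes$exonic_len)
    tseq <- random_dna(glen)
    names(tseq) <- genes

    M <- sum(molecules)
    gi <- rep(rep(seq_len(G), S), as.vector(molecules))
    si <- rep(rep(seq_len(S), each = G), as.vector(molecules))

    # UMIs: N segment over ACGT, V segment over ACG (non-T)
    draw_block <- function(n, len, alpha) {
      if (len == 0L) return(rep("", n))
      m <- matrix(sample(alpha, n * len, replace = TRUE), n, len)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    umi <- paste0(draw_block(M, rs$umi_n_len, c("A", "C", "G", "T")),
                  draw_block(M, rs$umi_v_len, c("A", "C", "G")))

    cat_lv <- c("normal", "unmapped", "multimapped", "intergenic")
    mol_cat <- sample(cat_lv, M, replace = TRUE,
                      prob = c(1 - sum(special), special))
    dup <- 1L + stats::rgeom(M, dup_p)

    # fragment placement with 3' bias (distance of fragment start from 3' end)
    L <- glen[gi]
    w <- pmin(read_len, L)
    d <- floor(stats::rexp(M, rate = 1 / bias_decay))
    p0 <- pmax(L - w - d, 0L)          # 0-based start, 5'->3' coords
    frag <- substr(tseq[gi], p0 + 1L, p0 + w)

    # genomic-spliced interval (left->right within the merged-exon body)
    strand <- gm$genes$strand[gi]
    ga <- ifelse(strand == "+", p0, L - p0 - w)
    gb <- ga + w                        # [ga, gb), 0-based spliced

    # decompose into genomic blocks and a CIGAR, per gene
    cigar <- character(M)
    gpos <- integer(M)                 # 1-based POS of first block
    for (g in unique(gi)) {
      ex <- gm$exons[[genes[g]]]
      exs <- IRanges::start(ex)
      wid <- IRanges::width(ex)
      co <- cumsum(wid)
      cs <- c(0L, co[-length(co)])
      sel <- which(gi == g)
      a <- ga[sel]; b <- gb[sel]
      cg <- rep("", length(sel))
      pos1 <- rep(NA_integer_, length(sel))
      prev_end <- rep(NA_integer_, length(sel))
      for (e in seq_along(exs)) {
        ov <- b > cs[e] & a < co[e]
        if (!any(ov)) next
        bs0 <- exs[e] + pmax(a[ov] - cs[e], 0L)            # genomic start
        bl <- pmin(b[ov], co[e]) - pmax(a[ov], cs[e])      # block length
        gapn <- bs0 - prev_end[ov] - 1L
        piece <- ifelse(is.na(prev_end[ov]), paste0(bl, "M"),
                        paste0(gapn, "N", bl, "M"))
        cg[ov] <- paste0(cg[ov], piece)
        pos1[ov] <- ifelse(is.na(pos1[ov]), bs0, pos1[ov])
        prev_end[ov] <- bs0 + bl - 1L
      }
      cigar[sel] <- cg
      gpos[sel] <- pos1
    }

    # expand molecules into reads
    ridx <- rep(seq_len(M), dup)
    R <- length(ridx)
    rep_no <- sequence(dup)
    qname <- sprintf("M%06d_R%02d", ridx, rep_no)
    r2seq <- frag[ridx]
    if (error_rate > 0) {
      nerr <- stats::rbinom(R, nchar(r2seq), error_rate)
      for (i in which(nerr > 0L)) {
        s <- strsplit(r2seq[i], "")[[1]]
        at <- sample.int(length(s), nerr[i])
        for (j in at) s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1L)
        r2seq[i] <- paste(s, collapse = "")
      }
    }
    r1seq <- paste0(bs$barcode[si[ridx]], umi[ridx])
    if (barcode_mismatch_frac > 0) {
      hit <- which(stats::runif(R) < barcode_mismatch_frac)
      for (i in hit) {
        at <- sample.int(rs$barcode_len, 1L)
        orig <- substr(r1seq[i], at, at)
        substr(r1seq[i], at, at) <-
          sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      }
    }

    # SAM records
    chrom <- gm$genes$chrom[gi]
    max_end <- tapply(
      vapply(gm$exons, function(e) max(IRanges::end(e)), numeric(1)),
      gm$genes$chrom, max)
    seqlen <- max_end + 20000
    inter_pos <- stats::setNames(as.integer(max_end + 10000), names(max_end))
    flag <- ifelse(strand[ridx] == "-", 16L, 0L)
    cat_r <- mol_cat[ridx]
    sam_seq <- r2seq
    minus <- strand[ridx] == "-" & cat_r != "unmapped"
    if (any(minus)) {
      sam_seq[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(sam_seq[minus])))
    }
    rname <- chrom[ridx]
    pos_out <- gpos[ridx]
    cig_out <- cigar[ridx]
    nh <- rep(1L, R)
    is_un <- cat_r == "unmapped"
    is_mm <- cat_r == "multimapped"
    is_ig <- cat_r == "intergenic"
    flag[is_un] <- 4L
    rname[is_un] <- "*"
    pos_out[is_un] <- 0L
    cig_out[is_un] <- "*"
    nh[is_mm] <- 2L
    pos_out[is_ig] <- inter_pos[chrom[ridx][is_ig]]
    cig_out[is_ig] <- paste0(nchar(r2seq[is_ig]), "M")
    flag[is_ig] <- 0L
    qual <- vapply(nchar(r2seq), function(n) strrep("I", n), character(1))
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
                   qname, flag, rname, pos_out,
                   ifelse(is_un, 0L, 255L), cig_out, sam_seq, qual, nh)
    # decoy secondary records for multimapped reads
    if (any(is_mm)) {
      mmi <- which(is_mm)
      rec2 <- sprintf("%s\t%d\t%s\t%d\t0\t%s\t*\t0\t0\t*\t*\tNH:i:2",
                      qname[mmi], bitwOr(flag[mmi], 256L), rname[mmi],
                      inter_pos[chrom[ridx][mmi]],
                      paste0(nchar(r2seq[mmi]), "M"))
      rec <- c(rec, rec2)
    }
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(seqlen),
                        as.integer(seqlen)))
    sam_path <- file.path(outdir, "alignments.sam")
    atomic_write_lines(c(header, rec), sam_path)

    # FASTQ files
    fq <- function(name, seq) {
      q <- vapply(nchar(seq), function(n) strrep("I", n), character(1))
      as.vector(rbind(paste0("@", name), seq, "+", q))
    }
    r1_path <- file.path(outdir, "R1.fastq")
    r2_path <- file.path(outdir, "R2.fastq")
    atomic_write_lines(fq(qname, r1seq), r1_path)
    atomic_write_lines(fq(qname, r2seq), r2_path)

    # ground truth
    normal <- mol_cat == "normal"
    mol_tab <- data.frame(sample_id = samples[si], gene_id = genes[gi],
                          umi = umi, dup = dup, category = mol_cat,
                          stringsAsFactors = FALSE)
    gf <- factor(genes[gi][normal], levels = genes)
    sf <- factor(samples[si][normal], levels = samples)
    expected_reads <- as.matrix(stats::xtabs(dup[normal] ~ gf + sf))
    uniq <- !duplicated(data.frame(g = gi, s = si, u = umi)[normal, ])
    expected_umis <- as.matrix(table(gf[uniq], sf[uniq]))
    dimnames(expected_reads) <- dimnames(expected_umis) <-
      list(genes, samples)
    per_read <- data.frame(qname = qname, sample_id = samples[si[ridx]],
                           gene_id = genes[gi[ridx]], umi = umi[ridx],
                           category = cat_r, stringsAsFactors = FALSE)
    config <- list(seed = seed, mean_molecules = mean_molecules,
                   mol_dispersion = mol_dispersion, dup_p = dup_p,
                   error_rate = error_rate, frac_unmapped = frac_unmapped,
                   frac_multimapped = frac_multimapped,
                   frac_intergenic = frac_intergenic,
                   bias_decay = bias_decay, read_len = read_len,
                   n_molecules = M, n_reads = R)
    utils::write.table(mol_tab, file.path(outdir, "truth_molecules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_atomic(config, file.path(outdir, "sim_config.json"))

    structure(
      list(r1 = r1_path, r2 = r2_path, sam = sam_path,
           truth = list(molecules = mol_tab,
                        expected_reads = matrix(as.integer(expected_reads),
                                                G, S,
                                                dimnames = list(genes, samples)),
                        expected_umis = matrix(as.integer(expected_umis),
                                               G, S,
                                               dimnames = list(genes, samples)),
                        per_read = per_read,
                        molecule_matrix = molecules),
           config = config),
      class = "SimLibrary")
  })
}
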