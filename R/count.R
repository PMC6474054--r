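#' Build paired read/UMI count matrices from tagged, assigned reads
#'
#' The core counting contract: for every (gene, sample) cell, `reads` is the
#' number of feature-assigned records and `umis` the number of distinct UMI
#' strings among them. UMIs containing `N` contribute to read counts but are
#' excluded from UMI counts (an ambiguous base makes molecule identity
#' uncertain). UMI collapse is exact string identity per (sample, gene); no
#' mismatch merging. Genes with zero counts are retained as explicit zero
#' rows, so the matrix dimensions are fixed by the gene model and sample
#' sheet.
#'
#' @param records data.frame with columns `sample_id`, `umi`, `gene_id`
#'   (one row per feature-assigned read).
#' @param gm A [load_gene_model()]; defines the gene (row) order.
#' @param bs A [barcode_set()]; defines the sample (column) order.
#'
#' @return An object of class `CountMatrices`: list with `genes`, `samples`,
#'   and integer matrices `reads` and `umis` (genes x samples), satisfying
#'   `umis <= reads` cell-wise.
#' @export
build_count_matrices <- function(records, gm, bs) {
  stopifnot(inherits(gm, "GeneModel"), inherits(bs, "BarcodeSet"))
  genes <- gm$genes$gene_id
  samples <- bs$sample_id
  if (nrow(records)) {
    unknown_g <- setdiff(records$gene_id, genes)
    if (length(unknown_g)) {
      stop("records reference gene(s) absent from the model: ",
           paste(utils::head(unknown_g, 3L), collapse = ", "))
    }
    unknown_s <- setdiff(records$sample_id, samples)
    if (length(unknown_s)) {
      stop("records reference sample(s) absent from the barcode set: ",
           paste(utils::head(unknown_s, 3L), collapse = ", "))
    }
  }
  gf <- factor(records$gene_id, levels = genes)
  sf <- factor(records$sample_id, levels = samples)
  reads <- as.matrix(table(gf, sf))
  umi_ok <- !grepl("N", records$umi, fixed = TRUE) & nzchar(records$umi)
  uniq <- !duplicated(records[c("sample_id", "gene_id", "umi")]) & umi_ok
  umis <- as.matrix(table(gf[uniq], sf[uniq]))
  dimnames(reads) <- dimnames(umis) <- list(genes, samples)
  structure(
    list(genes = genes, samples = samples,
         reads = matrix(as.integer(reads), nrow(reads), ncol(reads),
                        dimnames = dimnames(reads)),
         umis = matrix(as.integer(umis), nrow(umis), ncol(umis),
                       dimnames = dimnames(umis))),
    class = "CountMatrices"
  )
}

#' @export
print.CountMatrices <- function(x, ...) {
  cat("CountMatrices:", length(x$genes), "genes x", length(x$samples),
      "samples;", sum(x$reads), "reads,", sum(x$umis), "UMIs\n")
  invisible(x)
}

# Parse the "<name>_<BARCODE>_<UMI>" tag grammar off query names.
parse_qname_tags <- function(qname, rs) {
  m <- regmatches(qname, regexec("^(.*)_([ACGTN]+)_([ACGTN]*)$", qname))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("read name does not carry a _<BARCODE>_<UMI> tag: '",
         qname[which(bad)[1L]], "'")
  }
  barcode <- vapply(m, `[[`, "", 3L)
  umi <- vapply(m, `[[`, "", 4L)
  if (any(nchar(barcode) != rs$barcode_len) ||
      any(nchar(umi) != rs$umi_len)) {
    off <- which(nchar(barcode) != rs$barcode_len |
                   nchar(umi) != rs$umi_len)[1L]
    stop("tag on read '", qname[off], "' does not match the read structure")
  }
  data.frame(name = vapply(m, `[[`, "", 2L), barcode = barcode, umi = umi,
             stringsAsFactors = FALSE)
}

#' Count reads and UMIs per gene from aligned cDNA reads
#'
#' High-level counting front end. Sample and UMI tags are taken either from
#' the companion read-1 FASTQ (matched to alignments by query name, the
#' layout used when alignment precedes demultiplexing) or, when `r1` is
#' `NULL`, parsed from the `_<BARCODE>_<UMI>` suffix that [demultiplex()]
#' appends to read names. Reads are assigned to genes with [assign_reads()]
#' and tallied with [build_count_matrices()].
#'
#' @param aln_file SAM or BAM file of read-2 alignments.
#' @param gm A [load_gene_model()].
#' @param bs A [barcode_set()].
#' @param rs A [parse_read_structure()].
#' @param r1 Optional read-1 FASTQ path; when given, tags come from it.
#' @param strand_mode Passed to [assign_reads()].
#' @param max_mismatch Barcode mismatch tolerance when matching tags.
#'
#' @return List with `counts` (a `CountMatrices`), `assignments` (per-record
#'   data.frame with `sample_id` and `category`), and `log` (per-sample
#'   category totals, samples x categories, including an `unassigned`
#'   pseudo-sample row for reads whose barcode matched no sample).
#'
#' @importFrom Biostrings readDNAStringSet
#' @export
count_tagged_alignments <- function(aln_file, gm, bs, rs, r1 = NULL,
                                    strand_mode = "forward",
                                    max_mismatch = 0L) {
  aln <- read_alignments(aln_file)
  if (is.null(r1)) {
    tags <- parse_qname_tags(aln$qname, rs)
  } else {
    x1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
    ids <- sub("[/ ].*$", "", names(x1))
    et <- extract_tag(as.character(x1), rs)
    idx <- match(aln$qname, ids)
    if (anyNA(idx)) {
      stop("alignment query name(s) absent from the read-1 FASTQ: ",
           paste(utils::head(aln$qname[is.na(idx)], 3L), collapse = ", "))
    }
    tags <- data.frame(name = aln$qname,
                       barcode = et$barcode[idx],
                       umi = et$umi[idx],
                       stringsAsFactors = FALSE)
  }
  ok_tag <- !is.na(tags$barcode)
  sample_id <- rep(NA_character_, nrow(aln))
  if (any(ok_tag)) {
    mb <- match_barcode(tags$barcode[ok_tag], bs, max_mismatch)
    sample_id[ok_tag] <- mb$sample_id
  }
  aln <- assign_reads(aln, gm, strand_mode)
  feat <- aln$category == "feature" & !is.na(sample_id)
  records <- data.frame(sample_id = sample_id[feat],
                        umi = tags$umi[feat],
                        gene_id = aln$gene_id[feat],
                        stringsAsFactors = FALSE)
  cm <- build_count_matrices(records, gm, bs)
  cats <- c("feature", "no_feature", "ambiguous", "multimapped", "unmapped")
  sf <- factor(ifelse(is.na(sample_id), "unassigned", sample_id),
               levels = c(bs$sample_id, "unassigned"))
  log <- as.matrix(table(sf, factor(aln$category, levels = cats)))
  list(counts = cm,
       assignments = data.frame(qname = aln$qname, sample_id = sample_id,
                                category = aln$category,
                                gene_id = aln$gene_id,
                                stringsAsFactors = FALSE),
       log = log)
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' TSV layout: genes as rows with the gene id in the first column
#' (`gene_id`), one column per sample. MatrixMarket layout: coordinate
#' integer `.mtx` plus `genes.tsv` / `samples.tsv` sidecars; all-zero rows
#' are implicit in the sparse triplets but recoverable from the sidecar, so
#' the round trip is lossless.
#'
#' @param cm A `CountMatrices`.
#' @param dir Output directory.
#' @param format `"tsv"` or `"mtx"`.
#' @param which `"reads"` or `"umis"`.
#' @return Invisibly, the paths written.
#'
#' @importFrom Matrix writeMM Matrix
#' @export
write_count_matrix <- function(cm, dir, format = c("tsv", "mtx"),
                               which = c("reads", "umis")) {
  format <- match.arg(format)
  which <- match.arg(which)
  stopifnot(inherits(cm, "CountMatrices"))
  m <- cm[[which]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    path <- file.path(dir, paste0(which, ".tsv"))
    atomic_write(path, function(tmp) {
      df <- data.frame(gene_id = cm$genes, m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    invisible(path)
  } else {
    mtx <- file.path(dir, paste0(which, ".mtx"))
    atomic_write(mtx, function(tmp) {
      Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), tmp)
    })
    gpath <- file.path(dir, "genes.tsv")
    spath <- file.path(dir, "samples.tsv")
    atomic_write_lines(cm$genes, gpath)
    atomic_write_lines(cm$samples, spath)
    invisible(c(mtx, gpath, spath))
  }
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding the files.
#' @param format `"tsv"` or `"mtx"`.
#' @param which `"reads"` or `"umis"`.
#' @return An integer matrix with gene rownames and sample colnames.
#' @importFrom Matrix readMM
#' @export
read_count_matrix <- function(dir, format = c("tsv", "mtx"),
                              which = c("reads", "umis")) {
  format <- match.arg(format)
  which <- match.arg(which)
  if (format == "tsv") {
    df <- utils::read.delim(file.path(dir, paste0(which, ".tsv")),
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df$gene_id
    m
  } else {
    m <- as.matrix(Matrix::readMM(file.path(dir, paste0(which, ".mtx"))))
    storage.mode(m) <- "integer"
    rownames(m) <- readLines(file.path(dir, "genes.tsv"))
    colnames(m) <- readLines(file.path(dir, "samples.tsv"))
    m
  }
}
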