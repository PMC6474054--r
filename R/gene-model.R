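#' Load a gene model from a GTF file
#'
#' Exon records are grouped by gene, converted from the GTF's 1-based
#' inclusive coordinates to the 0-based half-open convention used internally
#' (via `GRanges`, which stores 1-based closed intervals; the conversion is a
#' representation detail), and overlapping or adjacent exons of one gene are
#' merged. The result is the reference against which aligned reads are
#' assigned.
#'
#' @param gtf Path to a GTF file.
#' @param feature_type Feature type to use (default `"exon"`).
#' @param id_attr Attribute naming the gene (default `"gene_id"`).
#'
#' @return An object of class `GeneModel`: a list with
#'   * `exons`: named `GRangesList`, one element per gene, merged exons
#'     sorted by position;
#'   * `genes`: data.frame with `gene_id`, `gene_name`, `chrom`, `strand`,
#'     `exonic_len` (merged exon width sum);
#'   * `seqlengths`: named vector of chromosome lengths when the GTF declares
#'     them, otherwise `NA`.
#'
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges reduce split strand seqnames width
#' @importFrom S4Vectors mcols
#' @export
load_gene_model <- function(gtf, feature_type = "exon", id_attr = "gene_id") {
  gr <- tryCatch(
    rtracklayer::import(gtf, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", gtf, "': ",
                             conditionMessage(e))
  )
  gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  if (length(gr) == 0L) {
    stop("no '", feature_type, "' features found in ", gtf)
  }
  ids <- S4Vectors::mcols(gr)[[id_attr]]
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    # report original line numbers of offending exon records
    raw <- readLines(gtf)
    feat <- grepl(paste0("\t", feature_type, "\t"), raw, fixed = TRUE)
    missing <- feat & !grepl(paste0(id_attr, " \""), raw, fixed = TRUE)
    stop("GTF '", gtf, "': ", feature_type, " record(s) without ", id_attr,
         " attribute on line(s) ",
         paste(utils::head(which(missing), 5L), collapse = ", "))
  }
  ids <- as.character(ids)
  exons <- GenomicRanges::reduce(GenomicRanges::split(gr, ids))
  gene_ids <- names(exons)
  ugr <- unlist(exons, use.names = FALSE)
  gidx <- rep(seq_along(exons), S4Vectors::elementNROWS(exons))
  first <- !duplicated(gidx)
  genes <- data.frame(
    gene_id = gene_ids,
    gene_name = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(ugr))[first],
    strand = as.character(GenomicRanges::strand(ugr))[first],
    exonic_len = as.numeric(tapply(GenomicRanges::width(ugr), gidx, sum)),
    stringsAsFactors = FALSE
  )
  names_attr <- S4Vectors::mcols(gr)$gene_name
  if (!is.null(names_attr)) {
    nm <- tapply(as.character(names_attr), ids, function(v) v[!is.na(v)][1L])
    has <- genes$gene_id %in% names(nm) & !is.na(nm[genes$gene_id])
    genes$gene_name[has] <- unname(nm[genes$gene_id[has]])
  }
  rownames(genes) <- NULL
  sl <- GenomeInfoDb::seqlengths(gr)
  structure(list(exons = exons, genes = genes, seqlengths = sl),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "sequence(s);",
      sum(x$genes$strand == "+"), "plus /",
      sum(x$genes$strand == "-"), "minus strand\n")
  invisible(x)
}
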