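#' Trim adapters and trailing poly-A from cDNA reads
#'
#' Removes the earliest occurrence of any adapter (and everything 3' of it),
#' then strips a trailing run of `A` of length at least `polya_min_run`.
#' Qualities are trimmed in lockstep. A read whose trimmed length falls below
#' `min_len` is flagged for discarding (`keep = FALSE`).
#'
#' @param seq,qual Character vectors of equal element-wise length: sequence
#'   and Phred quality string.
#' @param adapters Character vector of adapter sequences (uppercase DNA);
#'   empty by default, i.e. poly-A trimming only.
#' @param polya_min_run Minimum trailing A-run length to trim (default 10).
#' @param min_len Minimum surviving read length (default 20).
#'
#' @return A data.frame with columns `seq`, `qual`, `keep`.
#' @export
trim_read2 <- function(seq, qual, adapters = character(),
                       polya_min_run = 10L, min_len = 20L) {
  seq <- toupper(as.character(seq))
  qual <- as.character(qual)
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings must have equal lengths")
  }
  if (length(adapters)) adapters <- check_dna(adapters, "adapters")
  cut_at <- rep(NA_integer_, length(seq))  # first base to drop, 1-based
  for (ad in adapters) {
    pos <- regexpr(ad, seq, fixed = TRUE)
    hit <- pos > 0L
    cut_at[hit] <- pmin(cut_at[hit], pos[hit], na.rm = TRUE)
  }
  keep_len <- ifelse(is.na(cut_at), nchar(seq), cut_at - 1L)
  seq2 <- substr(seq, 1L, keep_len)
  # trailing poly-A run of >= polya_min_run
  if (polya_min_run > 0L) {
    run <- nchar(seq2) - nchar(sub("A*$", "", seq2))
    trim <- run >= polya_min_run
    keep_len <- ifelse(trim, nchar(seq2) - run, nchar(seq2))
    seq2 <- substr(seq2, 1L, keep_len)
  }
  data.frame(
    seq = seq2,
    qual = substr(qual, 1L, nchar(seq2)),
    keep = nchar(seq2) >= min_len,
    stringsAsFactors = FALSE
  )
}

#' Demultiplex paired barcode/cDNA FASTQ files into per-sample files
#'
#' Read 1 carries the sample barcode and UMI, read 2 the cDNA fragment. Each
#' read pair is assigned to a sample by barcode matching
#' ([match_barcode()]); the corresponding read-2 record is written to that
#' sample's FASTQ with `_<BARCODE>_<UMI>` appended to the read name, so that
#' downstream counting needs no access to the read-1 stream. Unassigned
#' read-2 records (unknown barcode, ambiguous match, or read 1 shorter than
#' the structure) go to `unassigned.fastq`.
#'
#' @param r1,r2 Paths to the read-1 and read-2 FASTQ files (plain or gzip).
#'   The two streams must contain the same read ids in the same order.
#' @param bs A [barcode_set()].
#' @param rs A [parse_read_structure()] layout; its barcode length must match
#'   the set's.
#' @param outdir Output directory (created if missing).
#' @param max_mismatch Barcode mismatch tolerance (default 0; see
#'   [match_barcode()]).
#' @param adapters,polya_min_run,min_len Optional read-2 trimming, applied
#'   before writing when `trim = TRUE`; see [trim_read2()].
#' @param trim Logical; apply read-2 trimming (default `FALSE`).
#' @param gzip Logical; gzip-compress output FASTQ files.
#'
#' @return A `DemuxSummary`: list with `total`, named `per_sample` counts,
#'   `unassigned`, `per_reason` breakdown, and `files` (paths written). The
#'   summary is also written to `demux_summary.json` and
#'   `demux_summary.tsv` in `outdir`. Conservation holds exactly:
#'   `total == sum(per_sample) + unassigned`.
#'
#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom S4Vectors mcols
#' @export
demultiplex <- function(r1, r2, bs, rs, outdir,
                        max_mismatch = 0L,
                        adapters = character(), polya_min_run = 10L,
                        min_len = 20L, trim = FALSE, gzip = FALSE) {
  stopifnot(inherits(bs, "BarcodeSet"), inherits(rs, "ReadStructure"))
  if (attr(bs, "barcode_len") != rs$barcode_len) {
    stop("barcode length of the sample sheet (", attr(bs, "barcode_len"),
         ") does not match the read structure (B", rs$barcode_len, ")")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2)) {
    stop("desynchronized streams: ", length(x1), " read-1 records vs ",
         length(x2), " read-2 records")
  }
  id1 <- sub("[/ ].*$", "", names(x1))
  id2 <- sub("[/ ].*$", "", names(x2))
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop("desynchronized streams at record ", bad[1L], ": read-1 id '",
         id1[bad[1L]], "' vs read-2 id '", id2[bad[1L]], "'")
  }
  n <- length(x1)

  if (n > 0L) {
    tags <- extract_tag(as.character(x1), rs)
    assign <- data.frame(sample_id = NA_character_,
                         reason = "too_short",
                         stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
    valid <- !tags$too_short
    if (any(valid)) {
      assign[valid, ] <- match_barcode(tags$barcode[valid], bs, max_mismatch)
    }
  } else {
    tags <- data.frame(barcode = character(), umi = character(),
                       too_short = logical())
    assign <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  }

  seq2 <- as.character(x2)
  qual2 <- as.character(S4Vectors::mcols(x2)$qualities)
  keep <- rep(TRUE, n)
  if (trim && n > 0L) {
    tr <- trim_read2(seq2, qual2, adapters, polya_min_run, min_len)
    seq2 <- tr$seq
    qual2 <- tr$qual
    keep <- tr$keep
  }

  assigned <- !is.na(assign$sample_id)
  # tag grammar: <original_name>_<BARCODE>_<UMI> on the id token
  names_out <- names(x2)
  if (any(assigned)) {
    tagged <- paste0(id2[assigned], "_", tags$barcode[assigned], "_",
                     tags$umi[assigned])
    rest <- sub("^[^ ]*", "", names(x2)[assigned])
    names_out[assigned] <- paste0(tagged, rest)
  }

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- character()
  write_subset <- function(idx, path) {
    atomic_write(path, function(tmp) {
      y <- Biostrings::DNAStringSet(seq2[idx])
      names(y) <- names_out[idx]
      Biostrings::writeXStringSet(y, tmp, format = "fastq",
                                  qualities = Biostrings::BStringSet(qual2[idx]),
                                  compress = gzip)
    })
  }
  for (s in bs$sample_id) {
    idx <- which(assigned & assign$sample_id == s & keep)
    path <- file.path(outdir, paste0(s, ext))
    write_subset(idx, path)
    files <- c(files, path)
  }
  un_path <- file.path(outdir, paste0("unassigned", ext))
  write_subset(which(!assigned), un_path)
  files <- c(files, un_path)

  per_sample <- vapply(bs$sample_id,
                       function(s) sum(assigned & assign$sample_id == s),
                       integer(1))
  reasons <- c("ok", "no_match", "ambiguous", "too_short")
  per_reason <- vapply(reasons, function(r) sum(assign$reason == r), integer(1))
  summary <- structure(
    list(total = n,
         per_sample = per_sample,
         unassigned = as.integer(n - sum(per_sample)),
         per_reason = per_reason,
         discarded_by_trim = as.integer(sum(assigned & !keep)),
         files = files),
    class = "DemuxSummary"
  )
  write_json_atomic(summary[c("total", "per_sample", "unassigned",
                              "per_reason", "discarded_by_trim")],
                    file.path(outdir, "demux_summary.json"))
  tsv <- c("category\tcount",
           paste0("total\t", n),
           paste0("sample:", names(per_sample), "\t", per_sample),
           paste0("unassigned\t", summary$unassigned),
           paste0("reason:", names(per_reason), "\t", per_reason))
  atomic_write_lines(tsv, file.path(outdir, "demux_summary.tsv"))
  summary
}

#' @export
print.DemuxSummary <- function(x, ...) {
  cat("DemuxSummary:", x$total, "read pairs;",
      sum(x$per_sample), "assigned across", length(x$per_sample), "samples;",
      x$unassigned, "unassigned\n")
  br <- x$per_reason
  cat("  reasons:", paste(names(br), br, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
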