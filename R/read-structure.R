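#' Parse a compact read-structure specification
#'
#' Read 1 of an early-multiplexed 3' tag library carries the sample barcode
#' followed by the UMI. The UMI itself has two segments: a fully random part
#' ("N" bases, any of ACGT) and a random non-T part ("V" bases, one of ACG)
#' that precedes the oligo-dT stretch of the capture primer. A structure is
#' written compactly as, e.g., `"B6N10V5"`: a 6 nt barcode, then a 15 nt UMI
#' (10 N + 5 V). Segments must appear in B, N, V order; N and V are optional.
#'
#' @param spec Character scalar such as `"B6N10V5"` or `"B6"` (UMI-free).
#'
#' @return An object of class `ReadStructure`: a list with integer fields
#'   `barcode_len`, `umi_n_len`, `umi_v_len`, plus derived `umi_len` and
#'   `total_len`.
#'
#' @examples
#' rs <- parse_read_structure("B6N10V5")
#' rs$total_len  # 21
#' @export
parse_read_structure <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec)) {
    stop("read structure must be a single string, e.g. \"B6N10V5\"")
  }
  m <- regmatches(spec, regexec("^B([0-9]+)(?:N([0-9]+))?(?:V([0-9]+))?$", spec))[[1]]
  if (length(m) == 0L) {
    # diagnose the first offending token for a usable message
    tok <- regmatches(spec, regexpr("^[A-Z][0-9]*", spec))
    tok <- if (length(tok)) tok else spec
    stop("malformed read structure '", spec, "': expected B<int>[N<int>][V<int>] ",
         "with segments in that order (offending token: '", tok, "')")
  }
  barcode_len <- as.integer(m[2])
  umi_n_len <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  umi_v_len <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  if (barcode_len < 1L) {
    stop("malformed read structure '", spec, "': barcode length must be >= 1 ",
         "(offending token: 'B", m[2], "')")
  }
  new_read_structure(barcode_len, umi_n_len, umi_v_len)
}

new_read_structure <- function(barcode_len, umi_n_len = 0L, umi_v_len = 0L) {
  structure(
    list(
      barcode_len = as.integer(barcode_len),
      umi_n_len = as.integer(umi_n_len),
      umi_v_len = as.integer(umi_v_len),
      umi_len = as.integer(umi_n_len + umi_v_len),
      total_len = as.integer(barcode_len + umi_n_len + umi_v_len)
    ),
    class = "ReadStructure"
  )
}

#' @export
print.ReadStructure <- function(x, ...) {
  cat(sprintf("ReadStructure: B%d", x$barcode_len))
  if (x$umi_n_len > 0L) cat(sprintf("N%d", x$umi_n_len))
  if (x$umi_v_len > 0L) cat(sprintf("V%d", x$umi_v_len))
  cat(sprintf("  (barcode %d nt, UMI %d nt, total %d nt)\n",
              x$barcode_len, x$umi_len, x$total_len))
  invisible(x)
}

#' Extract barcode and UMI from read-1 sequences
#'
#' Positional slicing of the read-1 sequence according to a
#' [parse_read_structure()] layout: the first `barcode_len` bases are the
#' sample barcode, the next `umi_len` bases the UMI. Sequences are uppercased.
#' Reads shorter than the full structure are flagged `too_short` and yield
#' `NA` barcode/UMI.
#'
#' @param read1_seq Character vector of read-1 sequences (any length).
#' @param rs A `ReadStructure`.
#'
#' @return A data.frame with columns `barcode`, `umi` (character, `NA` when
#'   too short) and `too_short` (logical), one row per input read.
#' @export
extract_tag <- function(read1_seq, rs) {
  stopifnot(inherits(rs, "ReadStructure"))
  seq <- toupper(as.character(read1_seq))
  too_short <- nchar(seq) < rs$total_len
  barcode <- ifelse(too_short, NA_character_, substr(seq, 1L, rs$barcode_len))
  umi <- ifelse(too_short, NA_character_,
                substr(seq, rs$barcode_len + 1L, rs$barcode_len + rs$umi_len))
  data.frame(barcode = barcode, umi = umi, too_short = too_short,
             stringsAsFactors = FALSE)
}
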