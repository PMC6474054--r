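#' Construct a validated barcode set
#'
#' A `BarcodeSet` maps sample identifiers to their DNA barcodes. All barcodes
#' must share one length, use only A/C/G/T, and both barcodes and sample ids
#' must be unique. Input order is preserved (it defines the sample order of
#' downstream count matrices).
#'
#' @param sample_id Character vector of sample identifiers.
#' @param barcode Character vector of DNA barcodes (same length as
#'   `sample_id`).
#'
#' @return A data.frame of class `BarcodeSet` with columns `sample_id` and
#'   `barcode`, and attribute `barcode_len`.
#' @export
barcode_set <- function(sample_id, barcode) {
  sample_id <- as.character(sample_id)
  barcode <- toupper(as.character(barcode))
  if (length(sample_id) != length(barcode)) {
    stop("sample_id and barcode must have equal length")
  }
  if (length(barcode) == 0L) stop("barcode set is empty")
  validate_barcode_rows(sample_id, barcode, line = seq_along(barcode))
  structure(
    data.frame(sample_id = sample_id, barcode = barcode,
               stringsAsFactors = FALSE),
    barcode_len = nchar(barcode[1L]),
    class = c("BarcodeSet", "data.frame")
  )
}

validate_barcode_rows <- function(sample_id, barcode, line) {
  problems <- character()
  bad <- !grepl("^[ACGT]+$", barcode)
  if (any(bad)) {
    problems <- c(problems, paste0("non-ACGT barcode on line(s) ",
                                   paste(line[bad], collapse = ", ")))
  }
  len <- nchar(barcode)
  if (length(unique(len[!bad])) > 1L) {
    off <- line[!bad & len != len[!bad][1L]]
    problems <- c(problems, paste0("ragged barcode lengths; line(s) ",
                                   paste(off, collapse = ", "),
                                   " differ from line ", line[!bad][1L]))
  }
  dup_bc <- duplicated(barcode)
  if (any(dup_bc)) {
    problems <- c(problems, paste0("duplicate barcode(s) on line(s) ",
                                   paste(line[dup_bc], collapse = ", ")))
  }
  dup_id <- duplicated(sample_id)
  if (any(dup_id)) {
    problems <- c(problems, paste0("duplicate sample_id(s) on line(s) ",
                                   paste(line[dup_id], collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid barcode set: ", paste(problems, collapse = "; "))
  }
  invisible(TRUE)
}

#' Load a sample sheet (TSV) into a BarcodeSet
#'
#' The sample sheet is a two-column tab-separated file,
#' `sample_id<TAB>barcode`, with optional comment/header lines starting with
#' `#`. Validation errors report the offending line numbers of the original
#' file.
#'
#' @param path Path to the TSV file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text Logical; if `TRUE`, `path` is treated as the sheet content
#'   itself (lines, or one string with embedded newlines).
#'
#' @return A [barcode_set()] in file order.
#' @export
load_sample_sheet <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(path, "\n", fixed = TRUE)) else readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) stop("sample sheet has no data lines")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stop("invalid barcode set: expected sample_id<TAB>barcode on line(s) ",
         paste(lineno[nfield < 2L], collapse = ", "))
  }
  sample_id <- trimws(vapply(parts, `[[`, "", 1L))
  barcode <- toupper(trimws(vapply(parts, `[[`, "", 2L)))
  validate_barcode_rows(sample_id, barcode, lineno)
  barcode_set(sample_id, barcode)
}

#' Match observed barcodes against a barcode set
#'
#' Each observed barcode is assigned to the sample whose barcode has the
#' minimal Hamming distance, provided that distance is at most `max_mismatch`
#' and strictly smaller than the distance to any other barcode. An `N` in the
#' observed sequence counts as a mismatch against every base. Ties within
#' tolerance are never resolved arbitrarily: they yield `ambiguous`.
#'
#' @param observed Character vector of observed barcode sequences, each of the
#'   set's barcode length.
#' @param bs A [barcode_set()].
#' @param max_mismatch Maximum Hamming distance accepted (default 0, strict).
#'
#' @return A data.frame with columns `sample_id` (character, `NA` when
#'   unassigned) and `reason` (`"ok"`, `"no_match"` or `"ambiguous"`).
#' @export
match_barcode <- function(observed, bs, max_mismatch = 0L) {
  stopifnot(inherits(bs, "BarcodeSet"), max_mismatch >= 0L)
  blen <- attr(bs, "barcode_len")
  observed <- toupper(as.character(observed))
  if (any(nchar(observed) != blen, na.rm = TRUE)) {
    stop("observed barcode length differs from the set's barcode length (",
         blen, ")")
  }
  n <- length(observed)
  k <- nrow(bs)
  if (n == 0L) {
    return(data.frame(sample_id = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  # distance matrix n x k via per-position character comparison
  obs_mat <- matrix(unlist(strsplit(observed, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, byrow = TRUE)
  dist <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    bc <- strsplit(bs$barcode[j], "", fixed = TRUE)[[1]]
    dist[, j] <- blen - rowSums(obs_mat == matrix(bc, n, blen, byrow = TRUE))
  }
  best <- apply(dist, 1L, min)
  n_best <- rowSums(dist == best)
  ok <- best <= max_mismatch & n_best == 1L
  ambiguous <- best <= max_mismatch & n_best > 1L
  idx <- max.col(-dist, ties.method = "first")
  data.frame(
    sample_id = ifelse(ok, bs$sample_id[idx], NA_character_),
    reason = ifelse(ok, "ok", ifelse(ambiguous, "ambiguous", "no_match")),
    stringsAsFactors = FALSE
  )
}
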