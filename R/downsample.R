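#' Seeded uniform downsampling of an alignment file
#'
#' Draws a uniform without-replacement sample of `target_n` distinct query
#' names and keeps every record of a selected name (so mates and secondary
#' lines of one read stay together), preserving record order. Sampling is
#' performed at the alignment level — not on FASTQ — so read-level
#' information such as duplicates and UMIs is retained for downstream
#' counting. The RNG is R's Mersenne-Twister with `sample.kind =
#' "Rejection"`, seeded from `seed`; the same seed always yields an
#' identical output file.
#'
#' @param aln_file Input SAM or BAM.
#' @param out_file Output path; written atomically, same format as chosen by
#'   extension (`.sam` or `.bam`).
#' @param target_n Number of distinct query names to keep (0 allowed).
#' @param seed Integer seed.
#'
#' @return Invisibly, a manifest list (input path and md5, seed, target_n,
#'   totals); also written as `<out_file>.manifest.json`.
#'
#' @importFrom Rsamtools asBam asSam
#' @export
downsample_alignments <- function(aln_file, out_file, target_n, seed) {
  lines <- read_sam_lines(aln_file)
  is_header <- grepl("^@", lines)
  body <- lines[!is_header]
  qn <- sub("\t.*$", "", body)
  names_all <- unique(qn)
  n_avail <- length(names_all)
  if (target_n > n_avail) {
    stop("target_n (", target_n, ") exceeds the number of distinct reads (",
         n_avail, ")")
  }
  keep_names <- with_local_seed(seed, {
    names_all[sort(sample.int(n_avail, target_n))]
  })
  out_lines <- c(lines[is_header], body[qn %in% keep_names])
  write_sam_lines(out_lines, out_file)
  manifest <- list(
    input = aln_file,
    input_md5 = unname(tools::md5sum(aln_file)),
    seed = seed,
    target_n = target_n,
    available_reads = n_avail,
    rng = "Mersenne-Twister/Rejection",
    output = out_file
  )
  write_json_atomic(manifest, paste0(out_file, ".manifest.json"))
  invisible(manifest)
}

#' Generate replicate downsamples of one alignment file
#'
#' Replicate `i` (of `k`) uses seed `base_seed + i - 1`, so `k = 1`
#' reproduces a single [downsample_alignments()] call at `base_seed`. Output
#' files are named `<prefix>_rep<i>.<ext>`; a manifest summarizing the set
#' is written alongside.
#'
#' @param aln_file Input SAM or BAM.
#' @param out_prefix Output path prefix (directory + stem).
#' @param target_n Reads per replicate.
#' @param k Number of replicates (default 10, the usual choice for
#'   depth-matched benchmarking).
#' @param base_seed Integer seed of the first replicate.
#' @param format `"sam"` (default) or `"bam"`.
#'
#' @return Character vector of the `k` output paths.
#' @export
replicate_downsamples <- function(aln_file, out_prefix, target_n, k = 10L,
                                  base_seed = 1L, format = "sam") {
  stopifnot(k >= 1L)
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- paste0(out_prefix, "_rep", i, ".", format)
    downsample_alignments(aln_file, out[i], target_n, base_seed + i - 1L)
  }
  write_json_atomic(
    list(input = aln_file, target_n = target_n, k = k,
         base_seed = base_seed, replicates = out),
    paste0(out_prefix, ".manifest.json"))
  out
}

# --- helpers ----------------------------------------------------------------

read_sam_lines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    sam <- Rsamtools::asSam(path, destination = tempfile(), overwrite = TRUE)
    on.exit(unlink(sam))
    readLines(sam)
  } else {
    readLines(path)
  }
}

write_sam_lines <- function(lines, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    tmp_sam <- tempfile(fileext = ".sam")
    writeLines(lines, tmp_sam)
    on.exit(unlink(tmp_sam))
    bam <- Rsamtools::asBam(tmp_sam, destination = sub("\\.bam$", "", path),
                            overwrite = TRUE, indexDestination = FALSE)
    invisible(bam)
  } else {
    atomic_write_lines(lines, path)
  }
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}
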