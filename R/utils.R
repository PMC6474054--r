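## Internal helpers shared across modules.

#' @importFrom jsonlite write_json toJSON
#' @importFrom tools md5sum file_ext
NULL

# Atomic file write: materialize in a temp file next to the destination,
# then rename. Rename within one directory is atomic on POSIX filesystems.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."),
                  tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file onto ", path)
  }
  invisible(path)
}

atomic_write_lines <- function(lines, path) {
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

# Uppercase DNA with basic alphabet check; `context` names the offender in errors.
check_dna <- function(x, context, allow_n = FALSE) {
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(context, ": non-DNA characters in ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
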