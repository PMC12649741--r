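# File readers/writers. Sequence parsing is delegated to Biostrings; these
# wrappers normalise to plain named character vectors so the rest of the
# package stays alphabet-checked base R.

#' Read a FASTA file as a named character vector
#'
#' Multi-record, line-wrapped FASTA. Record names are truncated at the first
#' whitespace, matching common genome-browser conventions.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(x) == 0L) stop("FASTA file '", path, "' contains no records", call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path Path to a 4-line-per-record FASTQ file.
#' @return Named character vector of upper-case DNA sequences. Duplicate read
#'   identifiers raise an error.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(x) == 0L) stop("FASTQ file '", path, "' contains no reads", call. = FALSE)
  reads <- toupper(as.character(x))
  names(reads) <- sub("\\s.*$", "", names(x))
  dup <- names(reads)[duplicated(names(reads))]
  if (length(dup)) {
    stop("duplicate read identifier(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  reads
}

#' Write reads to FASTQ with a fixed quality score
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality Phred quality assigned to every base (default 30, i.e. `?`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = 30L) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  qchar <- rawToChar(as.raw(33L + as.integer(quality)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(
      paste0("@", names(reads)[i]),
      reads[[i]],
      "+",
      strrep(qchar, nchar(reads[[i]]))
    ), con)
  }
  invisible(path)
}

# internal: accept a sequence string, named character vector, or FASTA path
.as_seq_input <- function(x, what = "sequence input") {
  if (is.character(x) && length(x) == 1L && !grepl("^[ACGTUNacgtun]*$", x) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- if (length(x) == 1L) "seq" else paste0("seq", seq_along(x))
    return(vapply(x, as_nucseq, "", USE.NAMES = TRUE))
  }
  stop(what, " must be a character vector of sequences or a FASTA path",
       call. = FALSE)
}
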