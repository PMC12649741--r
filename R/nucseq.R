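# Canonical DNA alphabet used throughout: A, C, G, T plus the ambiguity code N.
# Guides quoted as RNA (with U) are normalised to DNA on ingest and rendered
# back as RNA only for display/reports.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.BASES <- c("A", "C", "G", "T")

#' Validate and normalise a nucleotide sequence
#'
#' Upper-cases the input, converts RNA `U` to DNA `T`, and checks the result
#' against the `{A,C,G,T,N}` alphabet.
#'
#' @param s A single character string.
#' @param allow_empty Permit the empty string (default `TRUE`). Contexts that
#'   require a guide or protospacer pass `FALSE`.
#' @param allow_n Permit the ambiguity code `N` (default `TRUE`).
#' @param what Label used in error messages.
#' @return The normalised DNA string.
#' @export
as_nucseq <- function(s, allow_empty = TRUE, allow_n = TRUE, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- chartr("u", "U", toupper(s))
  s <- chartr("U", "T", s)
  if (!allow_empty && nchar(s) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  allowed <- if (allow_n) .DNA_ALPHABET else .BASES
  bad <- setdiff(unique(chars), allowed)
  if (length(bad)) {
    stop(what, " contains invalid character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s
}

#' Reverse complement
#'
#' Watson-Crick reverse complement over `{A,C,G,T,N}`; `N` maps to `N`.
#'
#' @param s A nucleotide sequence (DNA or RNA; RNA is normalised to DNA).
#' @return The reverse complement as a DNA string.
#' @examples
#' revcomp("ACGT")                  # palindrome
#' revcomp("CTTGTGGTAGTTGGAGCTGT")
#' @export
revcomp <- function(s) {
  s <- as_nucseq(s)
  if (nchar(s) == 0L) return(s)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Render a DNA guide as RNA
#'
#' @param s DNA sequence.
#' @return The same sequence with `T` replaced by `U`.
#' @export
dna_to_rna <- function(s) chartr("T", "U", as_nucseq(s))

#' Hamming distance between equal-length sequences
#'
#' Counts differing positions. `N` compared against anything (including `N`)
#' counts as a mismatch: an ambiguous genome base cannot be assumed to pair.
#'
#' @param a,b Equal-length nucleotide sequences.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming("TTTTGGGCTGGCCAAACTGC", "TTTTGGGCGGGCCAAACTGC")  # 1
#' @export
hamming <- function(a, b) {
  a <- as_nucseq(a)
  b <- as_nucseq(b)
  if (nchar(a) != nchar(b)) {
    stop("hamming() requires equal-length sequences (", nchar(a), " vs ",
         nchar(b), ")", call. = FALSE)
  }
  if (nchar(a) == 0L) return(0L)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# internal: mismatch vector between two character vectors (N always mismatches)
.mm_vec <- function(ca, cb) ca != cb | ca == "N" | cb == "N"

#' Convert between 5'->3' guide index and PAM index
#'
#' Guides are written 5'->3' with position 20 immediately adjacent to the PAM.
#' The field convention counts positions from the PAM instead: PAM index 1 is
#' the PAM-proximal base, 20 the PAM-distal end. For a 20-nt guide the two are
#' related by `p = 21 - i`.
#'
#' @param i 1-based 5'->3' string index (vectorised).
#' @param p PAM index in `[1, 20]` (vectorised).
#' @return The corresponding index on the other scale.
#' @examples
#' to_pam_index(20)   # 1: 3'-most guide base sits next to the PAM
#' to_pam_index(9)    # 12
#' from_pam_index(12) # 9
#' @export
to_pam_index <- function(i) {
  i <- .check_index(i, "5'->3' index")
  21L - i
}

#' @rdname to_pam_index
#' @export
from_pam_index <- function(p) {
  p <- .check_index(p, "PAM index")
  21L - p
}

.check_index <- function(i, what) {
  if (!is.numeric(i) || any(is.na(i)) || any(i != as.integer(i))) {
    stop(what, " must be integer-valued", call. = FALSE)
  }
  i <- as.integer(i)
  if (any(i < 1L | i > 20L)) {
    stop(what, " out of range [1, 20]: ", paste(i[i < 1L | i > 20L], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Construct an SNV allele pair
#'
#' Holds equal-length wild-type and mutant sequence contexts differing at a
#' single position. Only single-nucleotide variants are supported; indel
#' variants are rejected.
#'
#' @param wt_context,mut_context Equal-length nucleotide sequences.
#' @param variant_offset 0-based offset of the variant in both contexts. If
#'   omitted it is inferred as the unique differing position.
#' @return An object of class `allele_pair` with fields `wt_context`,
#'   `mut_context`, `variant_offset`, `wt_base`, `mut_base`.
#' @examples
#' allele_pair("TTTTGGGCTGGCCAAACTGC", "TTTTGGGCGGGCCAAACTGC")
#' @export
allele_pair <- function(wt_context, mut_context, variant_offset = NULL) {
  wt <- as_nucseq(wt_context, allow_empty = FALSE, what = "wt_context")
  mut <- as_nucseq(mut_context, allow_empty = FALSE, what = "mut_context")
  if (nchar(wt) != nchar(mut)) {
    stop("wild-type and mutant contexts must have equal length; ",
         "indel variants are not supported (SNVs only)", call. = FALSE)
  }
  cw <- strsplit(wt, "", fixed = TRUE)[[1L]]
  cm <- strsplit(mut, "", fixed = TRUE)[[1L]]
  diffs <- which(cw != cm)
  if (length(diffs) != 1L) {
    stop("contexts must differ at exactly one position (found ",
         length(diffs), " differences)", call. = FALSE)
  }
  inferred <- diffs - 1L
  if (is.null(variant_offset)) {
    variant_offset <- inferred
  } else if (as.integer(variant_offset) != inferred) {
    stop("variant_offset (", variant_offset, ") does not match the differing ",
         "position (", inferred, ")", call. = FALSE)
  }
  structure(
    list(
      wt_context = wt,
      mut_context = mut,
      variant_offset = as.integer(variant_offset),
      wt_base = cw[diffs],
      mut_base = cm[diffs]
    ),
    class = "allele_pair"
  )
}

#' @export
print.allele_pair <- function(x, ...) {
  cat("SNV allele pair (", nchar(x$wt_context), " nt context)\n", sep = "")
  cat("  variant: ", x$wt_base, ">", x$mut_base,
      " at 0-based offset ", x$variant_offset, "\n", sep = "")
  cat("  wt : ", x$wt_context, "\n  mut: ", x$mut_context, "\n", sep = "")
  invisible(x)
}
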