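# Off-target site enumeration under mismatch and bulge budgets.
#
# Alignments are evaluated in PAM-proximal coordinates: guide and candidate
# site are both read from the base adjacent to the PAM outwards, so index k of
# the working vectors equals PAM index k. A hit carries at most one contiguous
# bulge: a DNA bulge leaves extra unpaired bases in the genomic site (gap in
# the guide), an RNA bulge leaves extra unpaired guide bases (gap in the DNA).
# The bulge must be internal; by default it may not sit between the PAM and
# guide position 1.

.MAX_BULGE <- 5L

#' Mismatch/bulge search budget
#'
#' The default budget admits sites with up to 8 mismatches and no bulge, or up
#' to 2 mismatches with a single 1-5 nt DNA or RNA bulge.
#'
#' @param max_mm_no_bulge Maximum mismatches for bulge-free sites (default 8).
#' @param max_mm_with_bulge Maximum mismatches for bulged sites (default 2).
#' @param bulge_sizes Integer vector of admissible bulge sizes (default 1:5).
#' @param bulge_kinds Subset of `c("DNA", "RNA")` (default both).
#' @return A list of class `search_budget`.
#' @export
search_budget <- function(max_mm_no_bulge = 8L, max_mm_with_bulge = 2L,
                          bulge_sizes = 1:5, bulge_kinds = c("DNA", "RNA")) {
  stopifnot(max_mm_no_bulge >= 0L, max_mm_with_bulge >= 0L)
  bulge_sizes <- sort(unique(as.integer(bulge_sizes)))
  if (length(bulge_sizes) && (min(bulge_sizes) < 1L || max(bulge_sizes) > .MAX_BULGE)) {
    stop("bulge_sizes must lie in 1..", .MAX_BULGE, call. = FALSE)
  }
  bulge_kinds <- match.arg(bulge_kinds, c("DNA", "RNA"), several.ok = TRUE)
  structure(
    list(max_mm_no_bulge = as.integer(max_mm_no_bulge),
         max_mm_with_bulge = as.integer(max_mm_with_bulge),
         bulge_sizes = bulge_sizes,
         bulge_kinds = bulge_kinds),
    class = "search_budget"
  )
}

# internal: mismatch indicator with the N rule ('?' marks out-of-contig)
.mm_char <- function(a, b) a != b | a == "N" | b == "N" | a == "?" | b == "?"

# internal: align one guide to one site under a fixed bulge class.
# guide_pp / site_pp: character vectors in PAM-proximal order.
# Returns list(mm, j, mismatch_pam_indices) for the best bulge placement
# (most PAM-distal j among minimal... tie rule: j desc then mm asc is applied
# by the caller across sizes; here we return, for this size, the candidate
# list of (j, mm)).
.bulge_alignments <- function(guide_pp, site_pp, kind, size, allow_pam_adjacent) {
  L <- length(guide_pp)
  jmin <- if (allow_pam_adjacent) 0L else 1L
  if (kind == "none") {
    stopifnot(length(site_pp) == L)
    mm <- sum(.mm_char(site_pp, guide_pp))
    return(data.frame(j = NA_integer_, mm = mm))
  }
  if (kind == "DNA") {
    stopifnot(length(site_pp) == L + size)
    js <- jmin:(L - 1L)
    mm <- vapply(js, function(j) {
      pre <- if (j > 0L) sum(.mm_char(site_pp[seq_len(j)], guide_pp[seq_len(j)])) else 0L
      suf <- sum(.mm_char(site_pp[(j + size + 1L):(L + size)], guide_pp[(j + 1L):L]))
      pre + suf
    }, numeric(1))
    return(data.frame(j = js, mm = mm))
  }
  # RNA bulge: guide bases j+1..j+size unpaired
  stopifnot(length(site_pp) == L - size)
  jmax <- L - size - 1L
  if (jmax < jmin) return(data.frame(j = integer(), mm = numeric()))
  js <- jmin:jmax
  mm <- vapply(js, function(j) {
    pre <- if (j > 0L) sum(.mm_char(site_pp[seq_len(j)], guide_pp[seq_len(j)])) else 0L
    suf <- sum(.mm_char(site_pp[(j + 1L):(L - size)], guide_pp[(j + size + 1L):L]))
    pre + suf
  }, numeric(1))
  data.frame(j = js, mm = mm)
}

# internal: mismatch PAM indices for a fixed alignment
.mismatch_positions <- function(guide_pp, site_pp, kind, size, j) {
  L <- length(guide_pp)
  if (kind == "none") return(which(.mm_char(site_pp, guide_pp)))
  if (kind == "DNA") {
    site_idx <- c(seq_len(j), (j + size + 1L):(L + size))
    if (j == 0L) site_idx <- (size + 1L):(L + size)
    guide_idx <- seq_len(L)
    return(guide_idx[.mm_char(site_pp[site_idx], guide_pp[guide_idx])])
  }
  guide_idx <- c(seq_len(j), (j + size + 1L):L)
  if (j == 0L) guide_idx <- (size + 1L):L
  site_idx <- seq_len(L - size)
  guide_idx[.mm_char(site_pp[site_idx], guide_pp[guide_idx])]
}

# internal: enumerate PAM-anchored candidates on one contig/strand.
# Returns data frame of PAM start positions q (0-based, forward strand) and a
# character matrix E (n x 25) of site bases in PAM-proximal order.
.pam_candidates <- function(chars, strand, max_ext = 25L) {
  n <- length(chars)
  if (strand == "+") {
    gg <- which(chars[-n] == "G" & chars[-1L] == "G")  # 1-based pos of first G
    q <- gg - 2L                                       # 0-based PAM start
    q <- q[q >= 1L]                                    # need >=1 upstream base
  } else {
    cc <- which(chars[-n] == "C" & chars[-1L] == "C")
    q <- cc - 1L                                       # 0-based PAM start
    q <- q[q + 3L < n]                                 # need downstream room
  }
  if (!length(q)) {
    return(list(q = integer(), E = matrix(character(), 0L, max_ext)))
  }
  E <- matrix("?", length(q), max_ext)
  if (strand == "+") {
    for (k in seq_len(max_ext)) {
      idx <- q - k + 1L                                # 1-based forward index
      ok <- idx >= 1L
      E[ok, k] <- chars[idx[ok]]
    }
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (k in seq_len(max_ext)) {
      idx <- q + 3L + k                                # 1-based forward index
      ok <- idx <= n
      E[ok, k] <- comp[chars[idx[ok]]]
    }
  }
  list(q = q, E = E)
}

#' Enumerate candidate off-target sites for a guide
#'
#' PAM-anchored scan: every NGG on either strand of every contig is located,
#' the adjacent sequence is aligned to the guide without a bulge and with a
#' single DNA or RNA bulge of each admissible size, and every
#' (location, strand, bulge-kind) combination whose best alignment satisfies
#' the budget is reported once. Within a bulge kind, the reported alignment is
#' chosen deterministically: smallest budget-satisfying bulge, then fewest
#' mismatches, then the most PAM-distal bulge placement.
#'
#' @param guide 20-nt guide sequence.
#' @param genome Named character vector of contig sequences, or a FASTA path.
#' @param budget A [search_budget()].
#' @param allow_pam_adjacent_bulge Allow a bulge between the PAM and guide
#'   position 1 (default `FALSE`).
#' @return Data frame of class `offtarget_hits` with columns `contig_id`,
#'   `start`, `end` (0-based half-open, forward strand, covering site and
#'   PAM), `strand`, `site_seq` (site strand, 5'->3', PAM excluded), `pam`,
#'   `n_mismatches`, `bulge_kind` (`"none"`, `"DNA"`, `"RNA"`), `bulge_size`,
#'   `bulge_pam_index` (PAM index immediately proximal to the bulge; `NA` for
#'   bulge-free hits), `mismatch_pam_indices` (comma-joined).
#' @export
find_offtargets <- function(guide, genome, budget = search_budget(),
                            allow_pam_adjacent_bulge = FALSE) {
  guide <- as_nucseq(guide, allow_empty = FALSE, what = "guide")
  if (nchar(guide) != 20L) stop("guide must be 20 nt", call. = FALSE)
  stopifnot(inherits(budget, "search_budget"))
  genome <- .as_seq_input(genome, "genome")
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    stop("genome is empty", call. = FALSE)
  }
  g_pp <- rev(strsplit(guide, "", fixed = TRUE)[[1L]])  # PAM-proximal order
  L <- 20L

  classes <- list(list(kind = "none", size = 0L))
  for (kind in budget$bulge_kinds) {
    for (b in budget$bulge_sizes) {
      classes[[length(classes) + 1L]] <- list(kind = kind, size = b)
    }
  }

  hits <- list()
  for (contig in names(genome)) {
    seq <- as_nucseq(genome[[contig]])
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (n < L + 3L) next
    for (strand in c("+", "-")) {
      cand <- .pam_candidates(chars, strand)
      if (!length(cand$q)) next
      # room available for the site (bases 5' of the PAM on the site strand)
      room <- if (strand == "+") cand$q else n - (cand$q + 3L)

      # per-kind best alignment bookkeeping
      for (kind in unique(vapply(classes, `[[`, "", "kind"))) {
        sizes <- sort(unique(vapply(
          Filter(function(cl) cl$kind == kind, classes), `[[`, 0L, "size")))
        max_mm <- if (kind == "none") budget$max_mm_no_bulge else budget$max_mm_with_bulge
        chosen <- rep(FALSE, length(cand$q))
        for (b in sizes) {
          Ls <- L + if (kind == "DNA") b else if (kind == "RNA") -b else 0L
          ok_rows <- which(!chosen & room >= Ls)
          if (!length(ok_rows)) next
          for (r in ok_rows) {
            site_pp <- cand$E[r, seq_len(Ls)]
            al <- .bulge_alignments(g_pp, site_pp, kind, b, allow_pam_adjacent_bulge)
            pass <- al[al$mm <= max_mm, , drop = FALSE]
            if (!nrow(pass)) next
            # within this (location, kind, size): minimum mismatches,
            # ties broken by the most PAM-distal bulge placement
            if (kind == "none") {
              best <- pass[1L, ]
            } else {
              pass <- pass[order(pass$mm, -pass$j), , drop = FALSE]
              best <- pass[1L, ]
            }
            chosen[r] <- TRUE
            q <- cand$q[r]
            if (strand == "+") {
              start <- q - Ls; end <- q + 3L
              pam <- substr(seq, q + 1L, q + 3L)
            } else {
              start <- q; end <- q + 3L + Ls
              pam <- revcomp(substr(seq, q + 1L, q + 3L))
            }
            mmpos <- .mismatch_positions(g_pp, site_pp, kind, b, best$j)
            hits[[length(hits) + 1L]] <- data.frame(
              contig_id = contig,
              start = start, end = end, strand = strand,
              site_seq = paste(rev(site_pp), collapse = ""),
              pam = pam,
              n_mismatches = as.integer(best$mm),
              bulge_kind = kind,
              bulge_size = if (kind == "none") 0L else b,
              bulge_pam_index = if (kind == "none") NA_integer_ else as.integer(best$j),
              mismatch_pam_indices = paste(mmpos, collapse = ","),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }

  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    contig_id = character(), start = integer(), end = integer(),
    strand = character(), site_seq = character(), pam = character(),
    n_mismatches = integer(), bulge_kind = character(), bulge_size = integer(),
    bulge_pam_index = integer(), mismatch_pam_indices = character(),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig_id, out$start, out$strand, out$bulge_kind), ]
  rownames(out) <- NULL
  attr(out, "guide") <- guide
  attr(out, "budget") <- budget
  class(out) <- c("offtarget_hits", "data.frame")
  out
}

#' @export
print.offtarget_hits <- function(x, ...) {
  cat("Off-target hits for guide ", attr(x, "guide"), ": ", nrow(x), " site",
      if (nrow(x) != 1L) "s", "\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write off-target hits as TSV
#'
#' @param hits An `offtarget_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offtargets_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare off-target mismatch burden between an original and an ARROW guide
#'
#' For each off-target site found for the original guide, the ARROW guide is
#' re-aligned to the stored site sequence under the same bulge class (kind and
#' size), and the change in mismatch count is reported. When the two guides
#' differ by one base every delta lies in \{-1, 0, +1\}, and a site perfectly
#' matching the original guide always gains the intentional mismatch
#' (delta = +1).
#'
#' @param original,arrow 20-nt guide sequences of equal length.
#' @param hits_of_original `offtarget_hits` computed for `original`.
#' @param allow_pam_adjacent_bulge Must match the setting used for the search.
#' @return Data frame with the hit coordinates plus `mm_original`, `mm_arrow`,
#'   `delta`.
#' @export
compare_burden <- function(original, arrow, hits_of_original,
                           allow_pam_adjacent_bulge = FALSE) {
  original <- as_nucseq(original, allow_empty = FALSE, what = "original guide")
  arrow <- as_nucseq(arrow, allow_empty = FALSE, what = "ARROW guide")
  if (nchar(original) != nchar(arrow)) {
    stop("guides must have equal length", call. = FALSE)
  }
  a_pp <- rev(strsplit(arrow, "", fixed = TRUE)[[1L]])
  mm_arrow <- vapply(seq_len(nrow(hits_of_original)), function(i) {
    h <- hits_of_original[i, ]
    site_pp <- rev(strsplit(h$site_seq, "", fixed = TRUE)[[1L]])
    al <- .bulge_alignments(a_pp, site_pp, h$bulge_kind, h$bulge_size,
                            allow_pam_adjacent_bulge)
    as.integer(min(al$mm))
  }, integer(1))
  out <- data.frame(
    contig_id = hits_of_original$contig_id,
    start = hits_of_original$start,
    end = hits_of_original$end,
    strand = hits_of_original$strand,
    bulge_kind = hits_of_original$bulge_kind,
    mm_original = hits_of_original$n_mismatches,
    mm_arrow = mm_arrow,
    delta = mm_arrow - hits_of_original$n_mismatches,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Predict T7E1 cleavage fragment sizes
#'
#' Given an amplicon and the blunt-cut offset (3 bp 5' of the PAM; see
#' [cut_offset_from_site()]), returns the two fragment lengths produced by
#' cleavage at the cut site.
#'
#' @param amplicon_length Total amplicon length.
#' @param cut_offset 0-based between-base cut position, strictly inside the
#'   amplicon.
#' @return Integer vector of two fragment lengths summing to
#'   `amplicon_length`.
#' @examples
#' predict_t7e1_fragments(500, 200)  # 200 300
#' @export
predict_t7e1_fragments <- function(amplicon_length, cut_offset) {
  amplicon_length <- as.integer(amplicon_length)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset <= 0L || cut_offset >= amplicon_length) {
    stop("cut_offset must lie strictly inside the amplicon (0 < cut < ",
         amplicon_length, ")", call. = FALSE)
  }
  c(cut_offset, amplicon_length - cut_offset)
}
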