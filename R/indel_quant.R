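# Amplicon indel quantification.
#
# Reads are globally aligned to the amplicon reference with affine gap
# penalties (Biostrings); indel events are extracted from the gapped
# alignment, left-normalised so homopolymer gaps have a canonical position,
# and a read counts as edited when an indel intersects the window around the
# blunt cut site 3 bp 5' of the PAM. Substitutions never count as edits.

#' Construct an amplicon reference with a cut window
#'
#' @param sequence Amplicon sequence.
#' @param site Optional `protospacer_site` located within the amplicon; used
#'   to derive `cut_offset` via [cut_offset_from_site()].
#' @param cut_offset 0-based between-base position of the blunt cut. Required
#'   when `site` is `NULL`.
#' @param window_halfwidth Half-width of the edit-calling window around the
#'   cut (default 3 bp).
#' @return An object of class `amplicon_ref`.
#' @export
amplicon_ref <- function(sequence, site = NULL, cut_offset = NULL,
                         window_halfwidth = 3L) {
  sequence <- as_nucseq(sequence, allow_empty = FALSE, what = "amplicon")
  if (is.null(cut_offset)) {
    if (is.null(site)) stop("supply either `site` or `cut_offset`", call. = FALSE)
    cut_offset <- cut_offset_from_site(site)
  }
  cut_offset <- as.integer(cut_offset)
  window_halfwidth <- as.integer(window_halfwidth)
  n <- nchar(sequence)
  if (cut_offset <= 0L || cut_offset >= n) {
    stop("cut_offset must lie strictly inside the amplicon", call. = FALSE)
  }
  if (window_halfwidth < 0L || cut_offset - window_halfwidth < 0L ||
      cut_offset + window_halfwidth > n) {
    stop("cut window extends beyond the amplicon", call. = FALSE)
  }
  structure(
    list(sequence = sequence, site = site, cut_offset = cut_offset,
         window_halfwidth = window_halfwidth),
    class = "amplicon_ref"
  )
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat("Amplicon reference: ", nchar(x$sequence), " nt, cut offset ",
      x$cut_offset, ", edit window [", x$cut_offset - x$window_halfwidth, ", ",
      x$cut_offset + x$window_halfwidth, "]\n", sep = "")
  invisible(x)
}

# default alignment scoring (match, mismatch, gap open, gap extend)
.ALN_DEFAULTS <- list(match = 2, mismatch = -3, gap_open = 10, gap_extend = 1,
                      min_read_length = 50L, min_identity = 0.6)

# internal: align a set of reads to the reference; returns a list of
# per-read alignment records (gapped strings + extracted, left-normalised
# events + identity).
.align_many <- function(reads, ref, params = .ALN_DEFAULTS) {
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads),
    Biostrings::DNAString(ref$sequence),
    type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  lapply(seq_along(reads), function(i) {
    .alignment_record(reads[[i]], pat[[i]], sub[[i]], ref, params)
  })
}

# internal: build one alignment record from gapped strings
.alignment_record <- function(read, gapped_read, gapped_ref, ref, params) {
  too_short <- nchar(read) < params$min_read_length
  cr <- strsplit(gapped_read, "", fixed = TRUE)[[1L]]
  cf <- strsplit(gapped_ref, "", fixed = TRUE)[[1L]]
  ncol_aln <- length(cr)
  match_cols <- sum(cr == cf & cr != "-")
  identity <- match_cols / ncol_aln
  aligned <- !too_short && identity >= params$min_identity
  events <- if (aligned) {
    .normalize_events(.extract_events(cr, cf), ref$sequence)
  } else {
    .empty_events()
  }
  structure(
    list(read = read, gapped_read = gapped_read, gapped_ref = gapped_ref,
         identity = identity, aligned = aligned, events = events),
    class = "read_alignment"
  )
}

.empty_events <- function() {
  data.frame(kind = character(), ref_pos = integer(), length = integer(),
             inserted = character(), stringsAsFactors = FALSE)
}

# internal: walk alignment columns and emit raw indel events.
# ref_pos is 0-based: for deletions the first deleted reference base, for
# insertions the between-base point (number of reference bases consumed).
.extract_events <- function(cr, cf) {
  events <- .empty_events()
  ref_pos <- 0L
  i <- 1L
  n <- length(cr)
  while (i <= n) {
    if (cr[i] == "-") {                      # deletion run
      j <- i
      while (j <= n && cr[j] == "-") j <- j + 1L
      events <- rbind(events, data.frame(
        kind = "deletion", ref_pos = ref_pos, length = j - i,
        inserted = "", stringsAsFactors = FALSE))
      ref_pos <- ref_pos + (j - i)
      i <- j
    } else if (cf[i] == "-") {               # insertion run
      j <- i
      while (j <= n && cf[j] == "-") j <- j + 1L
      events <- rbind(events, data.frame(
        kind = "insertion", ref_pos = ref_pos, length = j - i,
        inserted = paste(cr[i:(j - 1L)], collapse = ""),
        stringsAsFactors = FALSE))
      i <- j
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  events
}

# internal: left-normalise indels (canonical leftmost position in
# homopolymer/repeat context), VCF style.
.normalize_events <- function(events, ref_seq) {
  if (!nrow(events)) return(events)
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  for (e in seq_len(nrow(events))) {
    p <- events$ref_pos[e]
    l <- events$length[e]
    if (events$kind[e] == "deletion") {
      # shift left while the base before the deletion equals its last base
      while (p > 0L && rc[p] == rc[p + l]) p <- p - 1L
    } else {
      s <- strsplit(events$inserted[e], "", fixed = TRUE)[[1L]]
      while (p > 0L && rc[p] == s[l]) {
        s <- c(rc[p], s[-l])
        p <- p - 1L
      }
      events$inserted[e] <- paste(s, collapse = "")
    }
    events$ref_pos[e] <- p
  }
  events
}

#' Align one read to an amplicon reference
#'
#' Global alignment with affine gap penalties (defaults: match +2, mismatch
#' -3, gap open -10, gap extend -1). Reads shorter than `min_read_length` or
#' aligning below `min_identity` are flagged unaligned. Indel events are
#' reported left-normalised.
#'
#' @param read Read sequence.
#' @param ref An [amplicon_ref()].
#' @param params Scoring/filter parameters; see `.ALN_DEFAULTS` in the
#'   package source for the fields (`match`, `mismatch`, `gap_open`,
#'   `gap_extend`, `min_read_length`, `min_identity`).
#' @return An object of class `read_alignment` with fields `gapped_read`,
#'   `gapped_ref`, `identity`, `aligned`, and `events` (data frame `kind`,
#'   `ref_pos`, `length`, `inserted`).
#' @export
align_read <- function(read, ref, params = .ALN_DEFAULTS) {
  read <- as_nucseq(read, allow_empty = FALSE, what = "read")
  stopifnot(inherits(ref, "amplicon_ref"))
  params <- utils::modifyList(.ALN_DEFAULTS, params)
  .align_many(stats::setNames(read, "read"), ref, params)[[1L]]
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("Read alignment: ", if (x$aligned) "aligned" else "unaligned",
      sprintf(" (identity %.1f%%)", 100 * x$identity), "\n", sep = "")
  if (nrow(x$events)) print.data.frame(x$events, row.names = FALSE)
  else cat("  no indel events\n")
  invisible(x)
}

#' Decide whether an aligned read is edited at the cut window
#'
#' A read is edited iff at least one indel event intersects the window
#' `[cut_offset - w, cut_offset + w]`: a deletion by interval overlap, an
#' insertion by its anchor point. Substitutions never count.
#'
#' @param alignment A `read_alignment` (or a bare event data frame).
#' @param ref The [amplicon_ref()] carrying the cut window.
#' @return List with `edited` (logical) and `events` (the window-intersecting
#'   indel events).
#' @export
call_window_edit <- function(alignment, ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  events <- if (inherits(alignment, "read_alignment")) alignment$events else alignment
  lo <- ref$cut_offset - ref$window_halfwidth
  hi <- ref$cut_offset + ref$window_halfwidth
  if (!nrow(events)) return(list(edited = FALSE, events = events[0L, ]))
  in_window <- vapply(seq_len(nrow(events)), function(i) {
    p <- events$ref_pos[i]
    if (events$kind[i] == "insertion") p >= lo && p <= hi
    else p <= hi && (p + events$length[i]) >= lo
  }, logical(1))
  list(edited = any(in_window), events = events[in_window, , drop = FALSE])
}

#' Indel frequency of an amplicon read set
#'
#' Aligns every read to the reference and computes the fraction of aligned
#' reads carrying a cut-window indel. Reads failing the length or identity
#' floor are counted as unaligned and excluded from the denominator.
#'
#' @param reads FASTQ path, or a named character vector of read sequences
#'   (duplicate names are rejected).
#' @param ref An [amplicon_ref()].
#' @param params Alignment parameters as in [align_read()].
#' @return An object of class `editing_summary` with fields `n_reads_total`,
#'   `n_reads_aligned`, `n_reads_edited`, `indel_frequency`,
#'   `event_histogram` (counts of window-intersecting events by kind and
#'   length), `window` and `per_read` (read id, aligned, edited).
#' @export
indel_frequency <- function(reads, ref, params = .ALN_DEFAULTS) {
  stopifnot(inherits(ref, "amplicon_ref"))
  params <- utils::modifyList(.ALN_DEFAULTS, params)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTUNacgtun]+$", reads)) {
    reads <- read_fastq(reads)
  }
  if (!is.character(reads) || length(reads) == 0L) {
    stop("no reads supplied", call. = FALSE)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  dup <- names(reads)[duplicated(names(reads))]
  if (length(dup)) {
    stop("duplicate read identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  reads <- vapply(reads, as_nucseq, "", USE.NAMES = TRUE)

  alns <- .align_many(reads, ref, params)
  calls <- lapply(alns, call_window_edit, ref = ref)
  aligned <- vapply(alns, `[[`, logical(1), "aligned")
  edited <- vapply(calls, `[[`, logical(1), "edited") & aligned

  hist_events <- do.call(rbind, lapply(calls[aligned], `[[`, "events"))
  event_histogram <- if (!is.null(hist_events) && nrow(hist_events)) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(hist_events))),
                            by = hist_events[c("kind", "length")], FUN = sum)
    agg[order(agg$kind, agg$length), ]
  } else {
    data.frame(kind = character(), length = integer(), n = integer())
  }

  n_aligned <- sum(aligned)
  structure(
    list(
      n_reads_total = length(reads),
      n_reads_aligned = n_aligned,
      n_reads_edited = sum(edited),
      indel_frequency = if (n_aligned > 0L) sum(edited) / n_aligned else NA_real_,
      event_histogram = event_histogram,
      window = c(lo = ref$cut_offset - ref$window_halfwidth,
                 hi = ref$cut_offset + ref$window_halfwidth),
      per_read = data.frame(id = names(reads), aligned = aligned,
                            edited = edited, stringsAsFactors = FALSE)
    ),
    class = "editing_summary"
  )
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("Editing summary\n")
  cat(sprintf("  reads: %d total, %d aligned, %d edited\n",
              x$n_reads_total, x$n_reads_aligned, x$n_reads_edited))
  cat(sprintf("  indel frequency: %.4f (window [%d, %d])\n",
              x$indel_frequency, x$window[["lo"]], x$window[["hi"]]))
  invisible(x)
}

#' Serialise an editing summary to JSON
#'
#' @param summary An `editing_summary`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
editing_summary_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "editing_summary"))
  x <- summary[c("n_reads_total", "n_reads_aligned", "n_reads_edited",
                 "indel_frequency")]
  x$window <- as.list(summary$window)
  x$event_histogram <- summary$event_histogram
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Allele-discrimination summary for one guide
#'
#' Compares editing on the mutant and wild-type alleles.
#'
#' @param mut,wt `editing_summary` objects (or bare rates) for the same guide
#'   assayed on the mutant and wild-type allele.
#' @return List with `mut_rate`, `wt_rate`, `ratio` (`Inf` when the wild-type
#'   rate is zero and the mutant rate positive) and `difference`.
#' @examples
#' discrimination_summary(0.08, 0.0028)  # ratio ~ 28.6
#' @export
discrimination_summary <- function(mut, wt) {
  rate <- function(x) {
    if (inherits(x, "editing_summary")) x$indel_frequency else as.numeric(x)
  }
  m <- rate(mut); w <- rate(wt)
  stopifnot(is.finite(m), is.finite(w), m >= 0, w >= 0)
  list(
    mut_rate = m,
    wt_rate = w,
    ratio = if (w == 0) {
      if (m > 0) Inf else NaN
    } else m / w,
    difference = m - w
  )
}

#' Classify a net indel length against a frameshift reporter
#'
#' The reporter carries an out-of-frame codon offset `k` (1 or 2) between the
#' target site and the fluorescent ORF; an edit restoring frame expresses the
#' reporter. An edit of net length `d` (insertions positive, deletions
#' negative) is in frame iff `(d + k) mod 3 == 0`.
#'
#' @param net_indel_length Integer vector of net indel lengths.
#' @param frame_offset Reporter frame offset, 1 (default) or 2.
#' @return Character vector, `"in_frame"` or `"out_of_frame"`.
#' @examples
#' classify_reporter_frame(-1)  # in_frame
#' classify_reporter_frame(0)   # out_of_frame: unedited reporter stays silent
#' @export
classify_reporter_frame <- function(net_indel_length, frame_offset = 1L) {
  if (!frame_offset %in% c(1L, 2L)) {
    stop("frame_offset must be 1 or 2", call. = FALSE)
  }
  d <- as.integer(net_indel_length)
  ifelse((d + frame_offset) %% 3L == 0L, "in_frame", "out_of_frame")
}

#' Unpaired t-test between replicate indel frequencies
#'
#' Convenience wrapper for comparing replicate editing frequencies between two
#' conditions (classical unpaired two-sample t-test, equal variances).
#'
#' @param x,y Numeric vectors of replicate frequencies.
#' @return An `htest` object from [stats::t.test()].
#' @export
replicate_ttest <- function(x, y) {
  stats::t.test(x, y, var.equal = TRUE)
}
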