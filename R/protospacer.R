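# Protospacer sites and PAM scanning.
#
# Coordinates are 0-based half-open on the forward strand of the contig, and a
# site always spans 23 bp: 20-nt protospacer plus NGG PAM in the orientation of
# the site's own strand. On '+' the protospacer occupies [start, start+20) and
# the PAM [start+20, start+23); on '-' the PAM occupies [start, start+3) on the
# forward strand and the stored protospacer/PAM strings are reverse-complements
# of the corresponding forward-strand windows.

.SITE_LEN <- 23L
.PROTO_LEN <- 20L

#' Construct a protospacer site record
#'
#' Validates the 23-bp protospacer+PAM geometry and the NGG PAM pattern.
#'
#' @param contig_id Contig name.
#' @param start 0-based start of the 23-bp window on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param protospacer 20-nt protospacer on the site's strand.
#' @param pam 3-nt PAM on the site's strand; must match NGG.
#' @param variant_pam_index Optional PAM index (1-20) of a variant covered by
#'   the protospacer, `NA` if not applicable.
#' @return A one-row data frame of class `protospacer_site` with columns
#'   `contig_id`, `start`, `end`, `strand`, `protospacer`, `pam`,
#'   `variant_pam_index`.
#' @export
protospacer_site <- function(contig_id, start, strand, protospacer, pam,
                             variant_pam_index = NA_integer_) {
  protospacer <- as_nucseq(protospacer, allow_empty = FALSE, what = "protospacer")
  pam <- as_nucseq(pam, allow_empty = FALSE, what = "PAM")
  if (nchar(protospacer) != .PROTO_LEN) {
    stop("protospacer must be 20 nt, got ", nchar(protospacer), call. = FALSE)
  }
  if (!grepl("^[ACGTN]GG$", pam)) {
    stop("PAM must match NGG, got ", pam, call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (!is.na(variant_pam_index)) variant_pam_index <- .check_index(variant_pam_index, "variant PAM index")
  out <- data.frame(
    contig_id = as.character(contig_id),
    start = as.integer(start),
    end = as.integer(start) + .SITE_LEN,
    strand = strand,
    protospacer = protospacer,
    pam = pam,
    variant_pam_index = as.integer(variant_pam_index),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protospacer_site", "data.frame")
  out
}

# internal: derive protospacer/PAM strings from a forward-strand 23-bp window
.site_from_window <- function(window, strand) {
  if (strand == "+") {
    list(protospacer = substr(window, 1L, 20L), pam = substr(window, 21L, 23L))
  } else {
    rc <- revcomp(window)
    list(protospacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L))
  }
}

#' Re-derive a site's protospacer and PAM from its coordinates
#'
#' Extracts the forward-strand window `[start, end)` from `context` and
#' orients it by `strand`. Used to check that stored site fields round-trip.
#'
#' @param context The contig/amplicon sequence the site was called on.
#' @param site A `protospacer_site` row.
#' @return List with elements `protospacer` and `pam`.
#' @export
site_sequences <- function(context, site) {
  context <- as_nucseq(context)
  window <- substr(context, site$start + 1L, site$end)
  .site_from_window(window, site$strand)
}

#' Scan a sequence for NGG-adjacent protospacers
#'
#' Finds every 20-nt window immediately 5' of an NGG PAM, on both strands.
#' When `variant_offset` is given, only sites whose protospacer covers that
#' position are returned, each annotated with the variant's PAM index.
#'
#' @param context Sequence to scan (string; length >= 23).
#' @param variant_offset Optional 0-based position of a variant that returned
#'   protospacers must cover. `NULL` returns all sites.
#' @param contig_id Contig name recorded in the output (default `"context"`).
#' @return A data frame of class `protospacer_site` (possibly 0 rows), columns
#'   as in [protospacer_site()].
#' @examples
#' scan_protospacers(paste0(strrep("A", 20), "TGG"), variant_offset = 19)
#' @export
scan_protospacers <- function(context, variant_offset = NULL, contig_id = "context") {
  context <- as_nucseq(context, allow_empty = FALSE, what = "context")
  n <- nchar(context)
  if (n < .SITE_LEN) {
    stop("context must be at least 23 nt to contain a protospacer+PAM",
         call. = FALSE)
  }
  if (!is.null(variant_offset)) {
    variant_offset <- as.integer(variant_offset)
    if (variant_offset < 0L || variant_offset >= n) {
      stop("variant_offset out of range [0, ", n - 1L, "]", call. = FALSE)
    }
  }
  chars <- strsplit(context, "", fixed = TRUE)[[1L]]

  rows <- list()
  add <- function(start, strand) {
    window <- substr(context, start + 1L, start + .SITE_LEN)
    parts <- .site_from_window(window, strand)
    vp <- NA_integer_
    if (!is.null(variant_offset)) {
      # protospacer genomic extent on forward strand
      proto_lo <- if (strand == "+") start else start + 3L
      proto_hi <- proto_lo + .PROTO_LEN            # half-open
      if (variant_offset < proto_lo || variant_offset >= proto_hi) return()
      i <- if (strand == "+") variant_offset - proto_lo + 1L
           else proto_hi - variant_offset          # 1-based 5'->3' on site strand
      vp <- to_pam_index(i)
    }
    rows[[length(rows) + 1L]] <<- protospacer_site(
      contig_id, start, strand, parts$protospacer, parts$pam, vp
    )
  }

  # forward: PAM at positions [s+20, s+23); need GG at s+21..s+22 (0-based)
  for (s in 0:(n - .SITE_LEN)) {
    if (chars[s + 22L] == "G" && chars[s + 23L] == "G") add(s, "+")
    # reverse: forward-strand CCN at [s, s+3) means NGG on the minus strand
    if (chars[s + 1L] == "C" && chars[s + 2L] == "C") add(s, "-")
  }

  if (!length(rows)) {
    out <- protospacer_site("x", 0L, "+", strrep("A", 20), "AGG")[0L, ]
    class(out) <- c("protospacer_site", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("protospacer_site", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write protospacer sites as a BED-like TSV
#'
#' Six columns: contig, start, end, name, pam_index_of_variant, strand.
#' Coordinates are 0-based half-open as in BED.
#'
#' @param sites A `protospacer_site` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(
    contig = sites$contig_id,
    start = sites$start,
    end = sites$end,
    name = paste0(sites$contig_id, ":", sites$start, sites$strand),
    pam_index_of_variant = ifelse(is.na(sites$variant_pam_index), ".",
                                  as.character(sites$variant_pam_index)),
    strand = sites$strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Blunt-cut offset of a site within its contig
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, between protospacer PAM indices 4
#' and 3. Returned as a 0-based between-base offset on the forward strand,
#' suitable for use as an amplicon cut position.
#'
#' @param site A `protospacer_site` row.
#' @return Integer offset.
#' @export
cut_offset_from_site <- function(site) {
  if (site$strand == "+") {
    pam_start <- site$start + .PROTO_LEN
    pam_start - 3L
  } else {
    site$start + 3L + 3L
  }
}
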