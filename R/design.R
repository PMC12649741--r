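# Intentional-mismatch guide design (the ARROW strategy).
#
# An ARROW guide starts from the guide perfectly matched to the mutant allele
# and carries exactly one deliberate mismatch at a chosen PAM-indexed position,
# so that it has one mismatch against the mutant protospacer and two against
# the wild-type protospacer. Which substitution to place at a position is
# driven by an empirical mismatch-tolerance table (H = highly tolerant,
# L = low tolerant).

#' Enumerate all single-base mismatch variants of a guide
#'
#' Each position of the guide can be substituted with any of the three other
#' bases, so a 20-nt guide yields 60 variants. Order is deterministic:
#' ascending PAM index, then base order A < C < G < T.
#'
#' @param guide Guide sequence (typically 20 nt) with no `N`.
#' @return Data frame with columns `pam_index`, `new_base`, `sequence`; one
#'   row per variant, `3 * nchar(guide)` rows in total.
#' @examples
#' nrow(enumerate_single_mismatch_variants("TTTTGGGCGGGCCAAACTGC"))  # 60
#' @export
enumerate_single_mismatch_variants <- function(guide) {
  guide <- as_nucseq(guide, allow_empty = FALSE, what = "guide")
  if (grepl("N", guide, fixed = TRUE)) {
    stop("guide contains N; ambiguous bases cannot be mismatched deterministically",
         call. = FALSE)
  }
  L <- nchar(guide)
  chars <- strsplit(guide, "", fixed = TRUE)[[1L]]
  rows <- vector("list", 3L * L)
  k <- 0L
  for (p in seq_len(L)) {                    # PAM index (1 = PAM-proximal)
    i <- L + 1L - p                          # 5'->3' string index
    for (b in .BASES) {
      if (b == chars[i]) next
      v <- chars
      v[i] <- b
      k <- k + 1L
      rows[[k]] <- data.frame(pam_index = p, new_base = b,
                              sequence = paste(v, collapse = ""),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate mismatch variants at selected PAM-indexed positions
#'
#' Exhaustive version of position-restricted mismatch screening: three
#' substitutions per requested position.
#'
#' @param guide 20-nt guide with no `N`.
#' @param positions Integer vector of PAM indices, or a preset name accepted by
#'   [position_preset()].
#' @return Data frame as in [enumerate_single_mismatch_variants()], restricted
#'   to `positions`.
#' @export
enumerate_at_positions <- function(guide, positions) {
  if (is.character(positions) && length(positions) == 1L) {
    positions <- position_preset(positions)
  }
  if (length(positions) == 0L) {
    return(enumerate_single_mismatch_variants(as_nucseq(guide, allow_empty = FALSE))[0L, ])
  }
  if (anyDuplicated(positions)) {
    stop("duplicate positions requested: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "),
         call. = FALSE)
  }
  positions <- .check_index(positions, "PAM index")
  all_v <- enumerate_single_mismatch_variants(guide)
  out <- all_v[all_v$pam_index %in% positions, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Named PAM-index position presets
#'
#' `"seed"` is the PAM-proximal set \{1, 3, 6\}, `"nonseed"` the PAM-distal
#' set \{9, 12, 15\}, and `"standard6"` their union — the six positions at
#' which mismatch tolerance is screened. `"design6"` is the variant used for
#' designs where position 12 is occupied by the target variant: 11 replaces 12.
#'
#' @param name One of `"seed"`, `"nonseed"`, `"standard6"`, `"design6"`.
#' @return Integer vector of PAM indices.
#' @export
position_preset <- function(name) {
  switch(match.arg(name, c("seed", "nonseed", "standard6", "design6")),
    seed = c(1L, 3L, 6L),
    nonseed = c(9L, 12L, 15L),
    standard6 = c(1L, 3L, 6L, 9L, 12L, 15L),
    design6 = c(1L, 3L, 6L, 9L, 11L, 15L)
  )
}

#' Default intentional-mismatch positions for a design
#'
#' Starts from the six screened positions \{1, 3, 6, 9, 12, 15\} and adjusts
#' for the variant's own PAM index, which is never a legal intentional-mismatch
#' position: a variant at 12 is replaced by the neighbouring position 11
#' (keeping six positions); a variant elsewhere in the set is dropped.
#'
#' @param variant_pam_index PAM index of the allele-discriminating variant, or
#'   `NULL` for the unadjusted six-position set.
#' @return Integer vector of PAM indices.
#' @examples
#' default_design_positions()     # 1 3 6 9 12 15
#' default_design_positions(12)   # 1 3 6 9 11 15  (EGFR L858R)
#' default_design_positions(1)    # 3 6 9 12 15    (KRAS G12V)
#' @export
default_design_positions <- function(variant_pam_index = NULL) {
  base <- position_preset("standard6")
  if (is.null(variant_pam_index)) return(base)
  p <- .check_index(variant_pam_index, "variant PAM index")
  if (p == 12L) return(position_preset("design6"))
  sort(setdiff(base, p))
}

#' Construct a mismatch-tolerance table
#'
#' Empirical indel rates measured for single-mismatch guides, keyed by
#' (PAM index, substituted base). Used to pick the highly tolerant (H) and low
#' tolerant (L) substitution at each position.
#'
#' @param entries Data frame with columns `pam_index`, `new_base`,
#'   `indel_rate` and optionally `source`.
#' @param provenance Free-text label describing where the rates came from.
#' @return The validated data frame with class `tolerance_table` and a
#'   `provenance` attribute.
#' @export
tolerance_table <- function(entries, provenance = "unspecified") {
  req <- c("pam_index", "new_base", "indel_rate")
  if (!all(req %in% names(entries))) {
    stop("tolerance table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  entries$pam_index <- .check_index(entries$pam_index, "pam_index")
  entries$new_base <- toupper(as.character(entries$new_base))
  if (!all(entries$new_base %in% .BASES)) {
    stop("new_base must be one of A, C, G, T", call. = FALSE)
  }
  if (!is.numeric(entries$indel_rate) ||
      any(entries$indel_rate < 0 | entries$indel_rate > 1)) {
    stop("indel_rate values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(entries[c("pam_index", "new_base")])) {
    stop("duplicate (pam_index, new_base) entries in tolerance table",
         call. = FALSE)
  }
  if (!"source" %in% names(entries)) entries$source <- provenance
  out <- as.data.frame(entries, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("tolerance_table", "data.frame")
  out
}

#' Read a mismatch-tolerance table from TSV
#'
#' Expected columns: `pam_index`, `new_base`, `indel_rate`, optionally
#' `source`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param provenance Provenance label; defaults to the file name.
#' @return A [tolerance_table()].
#' @export
read_tolerance_table <- function(path, provenance = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tolerance_table(df, provenance = provenance)
}

#' Classify mismatch tolerance per position
#'
#' At each requested position the substitution with the highest indel rate
#' (smallest reduction relative to the perfect guide) is labelled H, highly
#' tolerant; the substitution with the lowest rate (largest reduction) is
#' labelled L, low tolerant. Ties are broken by base order A < C < G < T and
#' flagged in the `tie_H` / `tie_L` columns.
#'
#' @param table A [tolerance_table()].
#' @param positions PAM indices to classify; every position must have at least
#'   two entries in `table`.
#' @return Data frame with one row per position: `pam_index`, `H_base`,
#'   `H_rate`, `L_base`, `L_rate`, `tie_H`, `tie_L`.
#' @export
classify_tolerance <- function(table, positions) {
  stopifnot(inherits(table, "tolerance_table"))
  positions <- .check_index(positions, "PAM index")
  rows <- lapply(positions, function(p) {
    sub <- table[table$pam_index == p, , drop = FALSE]
    if (nrow(sub) < 2L) {
      stop("tolerance table has fewer than 2 entries for position ", p,
           call. = FALSE)
    }
    sub <- sub[order(sub$new_base), , drop = FALSE]  # A<C<G<T tie order
    hi <- which(sub$indel_rate == max(sub$indel_rate))
    lo <- which(sub$indel_rate == min(sub$indel_rate))
    data.frame(
      pam_index = p,
      H_base = sub$new_base[hi[1L]],
      H_rate = sub$indel_rate[hi[1L]],
      L_base = sub$new_base[lo[1L]],
      L_rate = sub$indel_rate[lo[1L]],
      tie_H = length(hi) > 1L,
      tie_L = length(lo) > 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$tie_H | out$tie_L)) {
    tied <- out$pam_index[out$tie_H | out$tie_L]
    message("tolerance ties at position(s) ", paste(tied, collapse = ", "),
            "; broken by base order A<C<G<T")
  }
  out
}

# internal: apply one substitution at a PAM index
.substitute_at <- function(guide, pam_index, new_base) {
  i <- from_pam_index(pam_index)
  chars <- strsplit(guide, "", fixed = TRUE)[[1L]]
  if (chars[i] == new_base) {
    stop("substitution at PAM index ", pam_index, " does not change the base (",
         new_base, ")", call. = FALSE)
  }
  chars[i] <- new_base
  paste(chars, collapse = "")
}

#' Design allele-specific (ARROW) guides for an SNV
#'
#' Starting from the guide perfectly matched to the mutant allele at `site`,
#' introduces one intentional mismatch per output guide at each requested
#' position. Every emitted guide is verified to carry exactly one mismatch
#' against the mutant protospacer and exactly two against the wild-type
#' protospacer; guides failing this contract are never emitted.
#'
#' The variant's own position is forbidden (substituting there destroys allele
#' discrimination) unless `allow_variant_position = TRUE`.
#'
#' @param pair An [allele_pair()]; the site is located on the mutant context.
#' @param site A `protospacer_site` on the mutant context whose protospacer
#'   covers the variant. If `NULL`, the mutant context is scanned and the site
#'   is taken from `scan_protospacers()`; an error is raised if the scan is
#'   ambiguous.
#' @param positions PAM indices for the intentional mismatch; default
#'   [default_design_positions()] adjusted for the variant position.
#' @param table Optional [tolerance_table()]. When supplied, two guides (H and
#'   L) are designed per position, named `"P<pos>-H"` / `"P<pos>-L"`; without
#'   it, all three substitutions are emitted per position, named
#'   `"P<pos>-<base>"`.
#' @param allow_variant_position Override the forbidden-position rule (for
#'   exploration only).
#' @return Data frame of class `arrow_guides` with columns `name`, `sequence`,
#'   `rna`, `pam_index`, `new_base`, `label`, `mm_vs_mut`, `mm_vs_wt`.
#' @export
design_arrow_guides <- function(pair, site = NULL, positions = NULL,
                                table = NULL, allow_variant_position = FALSE) {
  stopifnot(inherits(pair, "allele_pair"))
  if (is.null(site)) {
    hits <- scan_protospacers(pair$mut_context, variant_offset = pair$variant_offset)
    if (nrow(hits) == 0L) {
      stop("no NGG protospacer covering the variant found on the mutant context",
           call. = FALSE)
    }
    if (nrow(hits) > 1L) {
      stop(nrow(hits), " candidate protospacers cover the variant; pass `site` ",
           "to select one (see scan_protospacers())", call. = FALSE)
    }
    site <- hits[1L, ]
  }
  mut_parts <- site_sequences(pair$mut_context, site)
  wt_parts <- site_sequences(pair$wt_context, site)
  mut_guide <- mut_parts$protospacer
  wt_proto <- wt_parts$protospacer
  if (hamming(mut_guide, wt_proto) != 1L) {
    stop("site protospacer does not cover the variant (wt/mut protospacers ",
         "differ at ", hamming(mut_guide, wt_proto), " positions)", call. = FALSE)
  }
  variant_p <- site$variant_pam_index
  if (is.na(variant_p)) {
    diff_i <- which(.mm_vec(strsplit(mut_guide, "", fixed = TRUE)[[1L]],
                            strsplit(wt_proto, "", fixed = TRUE)[[1L]]))
    variant_p <- to_pam_index(diff_i)
  }
  if (is.null(positions)) positions <- default_design_positions(variant_p)
  positions <- .check_index(positions, "PAM index")
  if (anyDuplicated(positions)) stop("duplicate design positions", call. = FALSE)
  if (!allow_variant_position && variant_p %in% positions) {
    stop("intentional mismatch at the variant position (PAM index ", variant_p,
         ") is forbidden: it would collapse allele discrimination",
         call. = FALSE)
  }

  specs <- if (!is.null(table)) {
    cls <- classify_tolerance(table, positions)
    do.call(rbind, lapply(seq_len(nrow(cls)), function(i) {
      data.frame(
        pam_index = rep(cls$pam_index[i], 2L),
        new_base = c(cls$H_base[i], cls$L_base[i]),
        label = c("H", "L"),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    v <- enumerate_at_positions(mut_guide, positions)
    data.frame(pam_index = v$pam_index, new_base = v$new_base,
               label = v$new_base, stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_len(nrow(specs)), function(i) {
    p <- specs$pam_index[i]
    b <- specs$new_base[i]
    seq <- .substitute_at(mut_guide, p, b)
    mm_mut <- hamming(seq, mut_guide)
    mm_wt <- hamming(seq, wt_proto)
    if (!(allow_variant_position && p == variant_p) &&
        (mm_mut != 1L || mm_wt != 2L)) {
      stop("designed guide at position ", p, " violates the 1-vs-mutant / ",
           "2-vs-wild-type contract (", mm_mut, " vs mut, ", mm_wt, " vs wt)",
           call. = FALSE)
    }
    data.frame(
      name = paste0("P", p, "-", specs$label[i]),
      sequence = seq,
      rna = dna_to_rna(seq),
      pam_index = p,
      new_base = b,
      label = specs$label[i],
      mm_vs_mut = mm_mut,
      mm_vs_wt = mm_wt,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mut_guide") <- mut_guide
  attr(out, "wt_protospacer") <- wt_proto
  attr(out, "variant_pam_index") <- variant_p
  class(out) <- c("arrow_guides", "data.frame")
  out
}

#' @export
print.arrow_guides <- function(x, ...) {
  cat("ARROW allele-specific guides (", nrow(x), " design",
      if (nrow(x) != 1L) "s", ")\n", sep = "")
  cat("  mutant-matched guide: 5'-", dna_to_rna(attr(x, "mut_guide")), "-3'\n",
      sep = "")
  cat("  variant PAM index:   ", attr(x, "variant_pam_index"), "\n", sep = "")
  print.data.frame(x[, c("name", "rna", "pam_index", "new_base",
                         "mm_vs_mut", "mm_vs_wt")], row.names = FALSE)
  invisible(x)
}

#' Write a guide design report as TSV
#'
#' @param guides An `arrow_guides` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(guides, path) {
  utils::write.table(as.data.frame(guides), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
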