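# Independent oracle implementations used to cross-check package results.
# These deliberately use different code paths (Biostrings, 5'->3' string
# arithmetic, exhaustive loops) from the implementations they validate.

# reverse complement via Biostrings
oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# naive protospacer scan: test every 23-nt window on both strands
oracle_scan <- function(context, variant_offset = NULL) {
  n <- nchar(context)
  out <- list()
  for (s in 0:(n - 23L)) {
    win <- substr(context, s + 1L, s + 23L)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") win else oracle_revcomp(win)
      pam <- substr(oriented, 21L, 23L)
      if (substr(pam, 2L, 3L) != "GG") next
      if (!is.null(variant_offset)) {
        plo <- if (strand == "+") s else s + 3L
        if (variant_offset < plo || variant_offset >= plo + 20L) next
      }
      out[[length(out) + 1L]] <- data.frame(
        start = s, strand = strand,
        protospacer = substr(oriented, 1L, 20L), pam = pam,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      protospacer = character(), pam = character()))
  }
  do.call(rbind, out)
}

# mismatch count between equal-length 5'->3' strings (N mismatches all)
oracle_mm <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# all single-bulge alignments of guide vs site in 5'->3' coordinates;
# returns the minimal mismatch count, and optionally the per-placement table.
# kind "DNA": site is longer than the guide by `size` (extra DNA bases);
# kind "RNA": site is shorter (unpaired guide bases). The bulge sits between
# PAM indices j and j+1 with j >= 1 (never PAM-adjacent), j expressed from
# the PAM-proximal (3') end.
oracle_bulge_mms <- function(guide, site, kind, size) {
  L <- nchar(guide)
  Ls <- nchar(site)
  res <- data.frame(j = integer(), mm = integer())
  if (kind == "none") {
    stopifnot(Ls == L)
    return(data.frame(j = NA_integer_, mm = oracle_mm(guide, site)))
  }
  if (kind == "DNA") {
    stopifnot(Ls == L + size)
    for (j in 1:(L - 1L)) {
      cut <- L - j                               # guide 5' block length
      gl <- substr(guide, 1L, cut)
      gr <- substr(guide, cut + 1L, L)
      sl <- substr(site, 1L, cut)
      sr <- substr(site, cut + size + 1L, Ls)
      res <- rbind(res, data.frame(j = j, mm = oracle_mm(gl, sl) + oracle_mm(gr, sr)))
    }
  } else {
    stopifnot(Ls == L - size)
    jmax <- L - size - 1L
    if (jmax < 1L) return(res)
    for (j in 1:jmax) {
      cut <- L - size - j                        # guide 5' block length
      gl <- substr(guide, 1L, cut)
      gr <- substr(guide, cut + size + 1L, L)
      sl <- substr(site, 1L, cut)
      sr <- substr(site, cut + 1L, Ls)
      res <- rbind(res, data.frame(j = j, mm = oracle_mm(gl, sl) + oracle_mm(gr, sr)))
    }
  }
  res
}

# naive off-target search. Scans the forward sequence for '+' hits and the
# reverse complement (with coordinate mirroring) for '-' hits; for each NGG
# and each bulge class tries every window/bulge placement. The reported
# alignment per (location, strand, kind) uses the same deterministic rule as
# the package: smallest budget-passing bulge, then fewest mismatches, then
# most PAM-distal placement.
oracle_offtargets <- function(guide, genome, max_mm_no_bulge, max_mm_with_bulge,
                              bulge_sizes = integer(),
                              bulge_kinds = c("DNA", "RNA")) {
  L <- nchar(guide)
  hits <- list()
  for (contig in names(genome)) {
    fwd <- genome[[contig]]
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      S <- if (strand == "+") fwd else oracle_revcomp(fwd)
      # PAM at 1-based [q+1, q+3] in S (q is the 0-based PAM start)
      for (q in 1:(n - 3L)) {
        if (substr(S, q + 2L, q + 3L) != "GG") next
        kinds <- c("none", intersect(bulge_kinds, c("DNA", "RNA")))
        for (kind in kinds) {
          sizes <- if (kind == "none") 0L else bulge_sizes
          max_mm <- if (kind == "none") max_mm_no_bulge else max_mm_with_bulge
          found <- FALSE
          for (b in sort(sizes)) {
            if (found) break
            Ls <- L + if (kind == "DNA") b else if (kind == "RNA") -b else 0L
            if (q - Ls < 0L) next
            site <- substr(S, q - Ls + 1L, q)
            al <- oracle_bulge_mms(guide, site, kind, b)
            al <- al[al$mm <= max_mm, , drop = FALSE]
            if (!nrow(al)) next
            al <- al[order(al$mm, -al$j), , drop = FALSE]
            found <- TRUE
            # map coordinates back to the forward strand
            if (strand == "+") {
              start <- q - Ls; end <- q + 3L
            } else {
              start <- n - (q + 3L); end <- n - (q - Ls)
            }
            hits[[length(hits) + 1L]] <- data.frame(
              contig_id = contig, start = start, end = end, strand = strand,
              site_seq = site, pam = substr(S, q + 1L, q + 3L),
              n_mismatches = al$mm[1L], bulge_kind = kind,
              bulge_size = b,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      site_seq = character(), pam = character(),
                      n_mismatches = integer(), bulge_kind = character(),
                      bulge_size = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$contig_id, out$start, out$strand, out$bulge_kind), ]
}

# canonical key for comparing hit sets
hit_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$contig_id, df$start, df$end, df$strand, df$bulge_kind,
             df$bulge_size, df$n_mismatches, df$site_seq, sep = "|"))
}

# shared worked-example bundle (cheap to rebuild per file)
wex <- worked_examples()
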