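# Deterministic synthetic-data generators: planted genomes for exercising the
# off-target search, simulated amplicon read sets for the indel quantifier,
# and the EGFR L858R / KRAS G12V worked examples used throughout the
# documentation and tests.

# internal: run code under a fixed RNG seed without disturbing the caller's
# RNG state. The generator algorithm is pinned so outputs are portable.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Simulation configuration
#'
#' Shared configuration object for the deterministic generators. Identical
#' configurations produce byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param genome_length Background genome length for [make_planted_genome()].
#' @param planted_sites List of site specifications from [planted_site()].
#' @param read_count Number of reads for [simulate_amplicon_reads()].
#' @param edited_fraction Probability that a simulated read carries a
#'   cut-window indel.
#' @param indel_length_distribution Named numeric vector of probabilities;
#'   names are net indel lengths (insertions positive, deletions negative).
#'   Must sum to 1. The default mixes 1-3 bp deletions and 1 bp insertions,
#'   the dominant SpCas9 repair outcomes at blunt cuts.
#' @param error_rate Per-base iid substitution error rate applied to every
#'   read (default 0.001, typical Illumina scale).
#' @param gc_content Background GC fraction for generated genomes
#'   (default 0.5).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 5000L,
                              planted_sites = list(),
                              read_count = 2000L,
                              edited_fraction = 0.4,
                              indel_length_distribution = c(
                                "-3" = 0.15, "-2" = 0.2, "-1" = 0.35, "1" = 0.3),
                              error_rate = 0.001,
                              gc_content = 0.5) {
  p <- as.numeric(indel_length_distribution)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("indel_length_distribution probabilities must sum to 1", call. = FALSE)
  }
  lens <- as.integer(names(indel_length_distribution))
  if (any(is.na(lens)) || any(lens == 0L)) {
    stop("indel lengths must be non-zero integers (insertions positive, ",
         "deletions negative)", call. = FALSE)
  }
  stopifnot(edited_fraction >= 0, edited_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            gc_content > 0, gc_content < 1)
  structure(
    list(seed = as.integer(seed),
         genome_length = as.integer(genome_length),
         planted_sites = planted_sites,
         read_count = as.integer(read_count),
         edited_fraction = edited_fraction,
         indel_length_distribution = stats::setNames(p, names(indel_length_distribution)),
         error_rate = error_rate,
         gc_content = gc_content),
    class = "simulation_config"
  )
}

#' Specify a site to plant in a synthetic genome
#'
#' The planted sequence is derived from `guide` by applying
#' `n_substitutions` random base changes and, optionally, a single bulge:
#' a DNA bulge inserts extra bases into the site, an RNA bulge deletes guide
#' bases from it.
#'
#' @param guide 20-nt guide the site derives from.
#' @param n_substitutions Number of mismatches to introduce (default 0).
#' @param bulge_kind `"none"`, `"DNA"` or `"RNA"`.
#' @param bulge_size Bulge length (1-5 when a bulge is requested).
#' @param strand Strand to plant on.
#' @param pam_n First base of the NGG PAM (default `"T"`).
#' @return A list of class `planted_site_spec`.
#' @export
planted_site <- function(guide, n_substitutions = 0L,
                         bulge_kind = c("none", "DNA", "RNA"),
                         bulge_size = 0L, strand = c("+", "-"), pam_n = "T") {
  guide <- as_nucseq(guide, allow_empty = FALSE, what = "guide")
  if (nchar(guide) != 20L) stop("guide must be 20 nt", call. = FALSE)
  bulge_kind <- match.arg(bulge_kind)
  strand <- match.arg(strand)
  if (bulge_kind != "none" && (bulge_size < 1L || bulge_size > .MAX_BULGE)) {
    stop("bulge_size must be 1..", .MAX_BULGE, " for a ", bulge_kind, " bulge",
         call. = FALSE)
  }
  structure(
    list(guide = guide, n_substitutions = as.integer(n_substitutions),
         bulge_kind = bulge_kind,
         bulge_size = if (bulge_kind == "none") 0L else as.integer(bulge_size),
         strand = strand, pam_n = pam_n),
    class = "planted_site_spec"
  )
}

# internal: realise a planted site sequence (protospacer-strand, 5'->3')
# from its spec using the current RNG stream. Substituted positions avoid the
# PAM-adjacent-bulge region convention used by the search (bulge j in 1..19).
.realise_site <- function(spec) {
  chars <- strsplit(spec$guide, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (spec$n_substitutions > 0L) {
    pos <- sample.int(L, spec$n_substitutions)
    for (i in pos) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  if (spec$bulge_kind == "DNA") {
    # extra DNA bases between PAM indices j and j+1 (string index boundary)
    j <- sample.int(L - 1L, 1L)                 # PAM index proximal to bulge
    i <- L - j                                  # insert after string index i
    ins <- sample(.BASES, spec$bulge_size, replace = TRUE)
    chars <- append(chars, ins, after = i)
  } else if (spec$bulge_kind == "RNA") {
    jmax <- L - spec$bulge_size - 1L
    j <- sample.int(jmax, 1L)
    # guide PAM indices j+1..j+size are unpaired: delete those site bases
    i_hi <- L - j                               # string index of PAM index j+1
    i_lo <- i_hi - spec$bulge_size + 1L
    chars <- chars[-(i_lo:i_hi)]
  }
  paste(chars, collapse = "")
}

#' Generate a random genome with planted target sites
#'
#' Background bases are drawn iid at the configured GC content; each planted
#' site (with an NGG PAM) is written at a recorded, non-overlapping locus.
#' The returned truth table lists the off-target hit each planted site is
#' expected to produce.
#'
#' @param cfg A [simulation_config()] with `planted_sites`.
#' @param fasta_path Optional path; when given the genome is also written as
#'   FASTA.
#' @param truth_path Optional path; when given the truth table is written as
#'   TSV.
#' @param contig_id Contig name (default `"synthetic1"`).
#' @return List with `genome` (named character vector) and `truth`
#'   (data frame with columns matching [find_offtargets()] output).
#' @export
make_planted_genome <- function(cfg, fasta_path = NULL, truth_path = NULL,
                                contig_id = "synthetic1") {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    n <- cfg$genome_length
    probs <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
               G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
    chars <- sample(names(probs), n, replace = TRUE, prob = probs)

    specs <- cfg$planted_sites
    k <- length(specs)
    truth_rows <- list()
    if (k > 0L) {
      site_seqs <- lapply(specs, .realise_site)
      lens <- vapply(site_seqs, nchar, 0L) + 3L
      # one slot per site, with margins, so sites never overlap
      slot <- n %/% k
      if (slot < max(lens) + 20L) {
        stop("genome too small for ", k, " planted site(s)", call. = FALSE)
      }
      for (i in seq_len(k)) {
        spec <- specs[[i]]
        full <- paste0(site_seqs[[i]], spec$pam_n, "GG")
        offset <- sample.int(slot - nchar(full) - 10L, 1L) + 5L
        pos <- (i - 1L) * slot + offset          # 0-based start of insertion
        planted <- if (spec$strand == "+") full else revcomp(full)
        chars[(pos + 1L):(pos + nchar(full))] <-
          strsplit(planted, "", fixed = TRUE)[[1L]]
        truth_rows[[i]] <- data.frame(
          contig_id = contig_id,
          start = pos, end = pos + nchar(full),
          strand = spec$strand,
          site_seq = site_seqs[[i]],
          pam = paste0(spec$pam_n, "GG"),
          n_mismatches = spec$n_substitutions,
          bulge_kind = spec$bulge_kind,
          bulge_size = spec$bulge_size,
          stringsAsFactors = FALSE
        )
      }
    }
    genome <- stats::setNames(paste(chars, collapse = ""), contig_id)
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(contig_id = character(), start = integer(), end = integer(),
                 strand = character(), site_seq = character(), pam = character(),
                 n_mismatches = integer(), bulge_kind = character(),
                 bulge_size = integer(), stringsAsFactors = FALSE)
    if (!is.null(fasta_path)) write_fasta(genome, fasta_path)
    if (!is.null(truth_path)) {
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(genome = genome, truth = truth)
  })
}

#' Simulate an edited amplicon read set
#'
#' Each read is a copy of the reference; with probability `edited_fraction`
#' one indel drawn from the configured length distribution is placed with its
#' anchor uniform in the cut window, then iid substitution errors are applied.
#' The truth table records each read's simulated edit status.
#'
#' @param ref An [amplicon_ref()].
#' @param cfg A [simulation_config()].
#' @param fastq_path Optional path; when given the reads are written as
#'   4-line FASTQ with fixed base quality 30.
#' @param truth_path Optional path; when given the truth table is written as
#'   JSON.
#' @return List with `reads` (named character vector) and `truth` (data frame
#'   `id`, `edited`, `kind`, `length`, `anchor`).
#' @export
simulate_amplicon_reads <- function(ref, cfg, fastq_path = NULL,
                                    truth_path = NULL) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    n <- cfg$read_count
    ref_chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
    L <- length(ref_chars)
    lo <- ref$cut_offset - ref$window_halfwidth
    hi <- ref$cut_offset + ref$window_halfwidth
    lens <- as.integer(names(cfg$indel_length_distribution))

    edited <- stats::runif(n) < cfg$edited_fraction
    ids <- sprintf("read%05d", seq_len(n))
    reads <- character(n)
    kind <- rep(NA_character_, n)
    length_out <- rep(NA_integer_, n)
    anchor <- rep(NA_integer_, n)

    for (i in seq_len(n)) {
      chars <- ref_chars
      if (edited[i]) {
        d <- lens[sample.int(length(lens), 1L,
                             prob = cfg$indel_length_distribution)]
        window <- lo:hi
        a <- window[sample.int(length(window), 1L)]  # between-base anchor
        if (d > 0L) {                           # insertion
          ins <- sample(.BASES, d, replace = TRUE)
          chars <- append(chars, ins, after = a)
          kind[i] <- "insertion"
        } else {                                # deletion of |d| bases at a
          dl <- -d
          a <- min(a, L - dl)                   # keep deletion inside the ref
          chars <- chars[-((a + 1L):(a + dl))]
          kind[i] <- "deletion"
        }
        length_out[i] <- abs(d)
        anchor[i] <- a
      }
      if (cfg$error_rate > 0) {
        hit <- which(stats::runif(length(chars)) < cfg$error_rate)
        for (h in hit) chars[h] <- sample(setdiff(.BASES, chars[h]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
    names(reads) <- ids
    truth <- data.frame(id = ids, edited = edited, kind = kind,
                        length = length_out, anchor = anchor,
                        stringsAsFactors = FALSE)
    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    if (!is.null(truth_path)) {
      writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                  na = "null"), truth_path)
    }
    list(reads = reads, truth = truth)
  })
}

#' Worked examples: EGFR L858R and KRAS G12V guide pairs
#'
#' The canonical allele-specific design examples: for each gene, the guide
#' perfectly matched to the wild-type allele and the guide perfectly matched
#' to the mutant allele (which differ by one base), the SNV allele pair with
#' genomic-style flanking context, and the protospacer site on the mutant
#' context. The EGFR L858R variant sits at PAM index 12 of its guide, the
#' KRAS G12V variant at PAM index 1.
#'
#' @return List with elements `egfr` and `kras` (each a list with `wt_guide`,
#'   `mut_guide`, `wt_guide_rna`, `mut_guide_rna`, `pair`, `site`,
#'   `variant_pam_index`) and `positions` (the named presets).
#' @export
worked_examples <- function() {
  build <- function(flank5, wt_guide, mut_guide, flank3) {
    wt_context <- paste0(flank5, wt_guide, flank3)
    mut_context <- paste0(flank5, mut_guide, flank3)
    pair <- allele_pair(wt_context, mut_context)
    sites <- scan_protospacers(pair$mut_context,
                               variant_offset = pair$variant_offset)
    site <- sites[sites$protospacer == mut_guide, , drop = FALSE][1L, ]
    list(
      wt_guide = wt_guide,
      mut_guide = mut_guide,
      wt_guide_rna = dna_to_rna(wt_guide),
      mut_guide_rna = dna_to_rna(mut_guide),
      pair = pair,
      site = site,
      variant_pam_index = site$variant_pam_index
    )
  }
  list(
    egfr = build(
      flank5 = "TCAAGATCACAGA",
      wt_guide = "TTTTGGGCTGGCCAAACTGC",   # 5'-UUUUGGGCUGGCCAAACUGC-3'
      mut_guide = "TTTTGGGCGGGCCAAACTGC",  # L858R: T>G at PAM index 12
      flank3 = "TGGGTGCGGAAGA"             # NGG PAM immediately 3'
    ),
    kras = build(
      flank5 = "ACTGAATATAAA",
      wt_guide = "CTTGTGGTAGTTGGAGCTGG",   # 5'-CUUGUGGUAGUUGGAGCUGG-3'
      mut_guide = "CTTGTGGTAGTTGGAGCTGT",  # G12V: G>T at PAM index 1
      flank3 = "TGGCGTAGGCAAG"
    ),
    positions = list(
      seed = position_preset("seed"),
      nonseed = position_preset("nonseed"),
      standard6 = position_preset("standard6"),
      design6 = position_preset("design6")
    )
  )
}
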