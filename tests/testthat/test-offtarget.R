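guide_k <- wex$kras$mut_guide

test_that("a planted perfect site is recovered exactly, with the oracle", {
  cfg <- simulation_config(seed = 101, genome_length = 5000,
                           planted_sites = list(planted_site(guide_k)))
  pg <- make_planted_genome(cfg)
  budget <- search_budget(max_mm_no_bulge = 0, max_mm_with_bulge = 0,
                          bulge_sizes = integer(), bulge_kinds = "DNA")
  hits <- find_offtargets(guide_k, pg$genome, budget)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, pg$truth$start)
  expect_identical(hits$n_mismatches, 0L)
  expect_identical(hits$bulge_kind, "none")
  oracle <- oracle_offtargets(guide_k, pg$genome, 0, 0)
  expect_identical(hit_key(as.data.frame(hits)), hit_key(oracle))
})

test_that("the mismatch budget is a sharp threshold", {
  cfg <- simulation_config(seed = 102, genome_length = 3000,
                           planted_sites = list(planted_site(guide_k, n_substitutions = 2)))
  pg <- make_planted_genome(cfg)
  tight <- find_offtargets(guide_k, pg$genome,
                           search_budget(max_mm_no_bulge = 1, bulge_sizes = integer()))
  expect_false(pg$truth$start %in% tight$start)
  loose <- find_offtargets(guide_k, pg$genome,
                           search_budget(max_mm_no_bulge = 2, bulge_sizes = integer()))
  row <- loose[loose$start == pg$truth$start, ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$n_mismatches, 2L)
})

test_that("a site with one deleted guide base is an RNA-bulge hit", {
  cfg <- simulation_config(seed = 103, genome_length = 3000,
                           planted_sites = list(
                             planted_site(guide_k, bulge_kind = "RNA", bulge_size = 1)))
  pg <- make_planted_genome(cfg)
  hits <- find_offtargets(guide_k, pg$genome,
                          search_budget(max_mm_no_bulge = 0, max_mm_with_bulge = 0,
                                        bulge_sizes = 1))
  row <- hits[hits$start == pg$truth$start & hits$bulge_kind == "RNA", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$bulge_size, 1L)
  expect_identical(row$n_mismatches, 0L)
  expect_identical(row$site_seq, pg$truth$site_seq)
})

test_that("search equals the naive all-windows oracle on seeded genomes", {
  seeds <- c(201, 202, 203)
  for (s in seeds) {
    cfg <- simulation_config(
      seed = s, genome_length = 2500, gc_content = 0.6,
      planted_sites = list(
        planted_site(guide_k),
        planted_site(guide_k, n_substitutions = 3, strand = "-"),
        planted_site(guide_k, bulge_kind = "DNA", bulge_size = 2),
        planted_site(guide_k, bulge_kind = "RNA", bulge_size = 2, strand = "-")))
    pg <- make_planted_genome(cfg)
    budget <- search_budget(max_mm_no_bulge = 4, max_mm_with_bulge = 2,
                            bulge_sizes = 1:2)
    hits <- find_offtargets(guide_k, pg$genome, budget)
    oracle <- oracle_offtargets(guide_k, pg$genome, 4, 2, bulge_sizes = 1:2)
    expect_identical(hit_key(as.data.frame(hits)), hit_key(oracle))
    # planted truth is contained in the hit set (PAM-anchored: within a kind
    # the search may report a smaller budget-passing bulge, shifting `start`)
    hit_anchor <- ifelse(hits$strand == "+", hits$end, hits$start)
    for (i in seq_len(nrow(pg$truth))) {
      t <- pg$truth[i, ]
      t_anchor <- if (t$strand == "+") t$end else t$start
      match_row <- hits[hit_anchor == t_anchor & hits$strand == t$strand &
                          hits$bulge_kind == t$bulge_kind, ]
      expect_gte(nrow(match_row), 1L)
    }
  }
})

test_that("hit counts are monotone in the mismatch and bulge budgets", {
  cfg <- simulation_config(seed = 301, genome_length = 4000, gc_content = 0.6,
                           planted_sites = list(planted_site(guide_k, n_substitutions = 1)))
  pg <- make_planted_genome(cfg)
  counts_mm <- vapply(0:5, function(m) {
    nrow(find_offtargets(guide_k, pg$genome,
                         search_budget(max_mm_no_bulge = m, bulge_sizes = integer())))
  }, integer(1))
  expect_true(all(diff(counts_mm) >= 0L))
  counts_bulge <- vapply(1:3, function(b) {
    nrow(find_offtargets(guide_k, pg$genome,
                         search_budget(max_mm_no_bulge = 0, max_mm_with_bulge = 2,
                                       bulge_sizes = seq_len(b))))
  }, integer(1))
  expect_true(all(diff(counts_bulge) >= 0L))
})

test_that("searching the reverse-complemented genome mirrors the hits", {
  cfg <- simulation_config(seed = 302, genome_length = 3000, gc_content = 0.6,
                           planted_sites = list(
                             planted_site(guide_k, n_substitutions = 2),
                             planted_site(guide_k, n_substitutions = 4, strand = "-")))
  pg <- make_planted_genome(cfg)
  budget <- search_budget(max_mm_no_bulge = 4, max_mm_with_bulge = 1, bulge_sizes = 1)
  fwd <- find_offtargets(guide_k, pg$genome, budget)
  n <- nchar(pg$genome[[1]])
  rc_genome <- stats::setNames(revcomp(pg$genome[[1]]), names(pg$genome))
  rev <- find_offtargets(guide_k, rc_genome, budget)
  mirrored <- data.frame(
    contig_id = rev$contig_id,
    start = n - rev$end, end = n - rev$start,
    strand = ifelse(rev$strand == "+", "-", "+"),
    site_seq = rev$site_seq, pam = rev$pam,
    n_mismatches = rev$n_mismatches, bulge_kind = rev$bulge_kind,
    bulge_size = rev$bulge_size, stringsAsFactors = FALSE)
  expect_identical(hit_key(as.data.frame(fwd)), hit_key(mirrored))
})

test_that("burden deltas are recounted correctly and bounded", {
  ex <- wex$kras
  arrow <- design_arrow_guides(ex$pair, site = ex$site)
  arrow_seq <- arrow$sequence[arrow$pam_index == 6][1]
  cfg <- simulation_config(seed = 401, genome_length = 4000, gc_content = 0.55,
                           planted_sites = list(
                             planted_site(guide_k),
                             planted_site(guide_k, n_substitutions = 3),
                             planted_site(guide_k, n_substitutions = 4, strand = "-")))
  pg <- make_planted_genome(cfg)
  hits <- find_offtargets(guide_k, pg$genome,
                          search_budget(max_mm_no_bulge = 5, bulge_sizes = integer()))
  burden <- compare_burden(guide_k, arrow_seq, hits)
  expect_true(all(burden$delta %in% c(-1L, 0L, 1L)))
  # the perfect on-target site must gain exactly the intentional mismatch
  perfect <- burden[burden$mm_original == 0L, ]
  expect_gte(nrow(perfect), 1L)
  expect_true(all(perfect$delta == 1L))
  # independent position-by-position recount
  for (i in seq_len(nrow(burden))) {
    site5p <- hits$site_seq[i]
    expect_identical(burden$mm_arrow[i],
                     min(oracle_bulge_mms(arrow_seq, site5p, hits$bulge_kind[i],
                                          hits$bulge_size[i])$mm))
  }
  expect_error(compare_burden(guide_k, substr(guide_k, 1, 19), hits),
               "equal length")
})

test_that("a site already mismatched at the intentional position loses one", {
  # original guide mismatches the site at PAM index 6; the ARROW base matches
  site5p <- guide_k
  substr(site5p, 15, 15) <- "G"                       # PAM index 6 = index 15
  expect_identical(hamming(site5p, guide_k), 1L)
  set.seed(67)
  genome <- c(chr = paste0(random_dna(50), site5p, "TGG", random_dna(50)))
  hits <- find_offtargets(guide_k, genome,
                          search_budget(max_mm_no_bulge = 2, bulge_sizes = integer()))
  row <- hits[hits$site_seq == site5p, ]
  expect_identical(row$n_mismatches, 1L)
  arrow_match <- guide_k
  substr(arrow_match, 15, 15) <- "G"                  # intentional mismatch = site base
  burden <- compare_burden(guide_k, arrow_match, row)
  expect_identical(burden$delta, -1L)
})

test_that("T7E1 fragment prediction conserves the amplicon length", {
  expect_identical(predict_t7e1_fragments(500, 200), c(200L, 300L))
  set.seed(7)
  for (i in 1:10) {
    len <- sample(100:1000, 1)
    cut <- sample(seq_len(len - 1), 1)
    expect_identical(sum(predict_t7e1_fragments(len, cut)), len)
  }
  expect_error(predict_t7e1_fragments(100, 0), "strictly inside")
  expect_error(predict_t7e1_fragments(100, 100), "strictly inside")
  # cut offset derived from a site whose PAM starts at amplicon position 100
  site <- protospacer_site("amp", 80L, "+", strrep("A", 20), "AGG")
  expect_identical(predict_t7e1_fragments(400, cut_offset_from_site(site)),
                   c(97L, 303L))
})
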