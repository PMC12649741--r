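test_that("single-mismatch enumeration yields all 60 variants, ordered", {
  guide <- wex$egfr$mut_guide
  v <- enumerate_single_mismatch_variants(guide)
  expect_identical(nrow(v), 60L)
  expect_identical(anyDuplicated(v$sequence), 0L)
  expect_true(all(vapply(v$sequence, hamming, 0L, b = guide) == 1L))
  # deterministic order: ascending PAM index, then A < C < G < T
  expect_identical(v$pam_index, rep(1:20, each = 3L))
  expect_true(all(tapply(v$new_base, v$pam_index, function(b) !is.unsorted(b))))
})

test_that("variants at PAM index 1 of a poly-A guide substitute the 3' base", {
  v <- enumerate_single_mismatch_variants(strrep("A", 20))
  p1 <- v[v$pam_index == 1L, ]
  expect_identical(p1$new_base, c("C", "G", "T"))
  expect_identical(unique(substr(p1$sequence, 1, 19)), strrep("A", 19))
  expect_identical(substr(p1$sequence, 20, 20), c("C", "G", "T"))
})

test_that("enumeration size is 3 per position for any guide length", {
  set.seed(5)
  for (L in 1:20) {
    g <- random_dna(L)
    v <- enumerate_single_mismatch_variants(g)
    expect_identical(nrow(v), 3L * L)
    expect_true(all(vapply(v$sequence, hamming, 0L, b = g) == 1L))
  }
  expect_error(enumerate_single_mismatch_variants("ACGTNACGTACGTACGTACG"),
               "ambiguous")
})

test_that("position-restricted enumeration is a filtered subset of the 60", {
  guide <- wex$kras$mut_guide
  v6 <- enumerate_at_positions(guide, c(1, 3, 6, 9, 12, 15))
  expect_identical(nrow(v6), 18L)
  full <- enumerate_single_mismatch_variants(guide)
  expect_identical(v6, {
    f <- full[full$pam_index %in% c(1, 3, 6, 9, 12, 15), ]
    rownames(f) <- NULL
    f
  })
  expect_identical(nrow(enumerate_at_positions(guide, integer())), 0L)
  expect_identical(enumerate_at_positions(guide, "seed"),
                   enumerate_at_positions(guide, c(1, 3, 6)))
  expect_error(enumerate_at_positions(guide, c(3, 3)), "duplicate")
  expect_error(enumerate_at_positions(guide, c(0, 5)), "out of range")
})

test_that("position presets match the screened seed/non-seed scheme", {
  expect_identical(position_preset("seed"), c(1L, 3L, 6L))
  expect_identical(position_preset("nonseed"), c(9L, 12L, 15L))
  expect_identical(position_preset("standard6"), c(1L, 3L, 6L, 9L, 12L, 15L))
  expect_identical(default_design_positions(), c(1L, 3L, 6L, 9L, 12L, 15L))
  expect_identical(default_design_positions(12), c(1L, 3L, 6L, 9L, 11L, 15L))
  expect_identical(default_design_positions(1), c(3L, 6L, 9L, 12L, 15L))
  expect_length(default_design_positions(), 6L)
  expect_length(default_design_positions(12), 6L)
})

make_table <- function(rates) {
  # rates: named list position -> named numeric vector base -> rate
  rows <- do.call(rbind, lapply(names(rates), function(p) {
    data.frame(pam_index = as.integer(p), new_base = names(rates[[p]]),
               indel_rate = as.numeric(rates[[p]]), stringsAsFactors = FALSE)
  }))
  tolerance_table(rows, provenance = "synthetic unit-test rates")
}

test_that("tolerance classification takes argmax as H and argmin as L", {
  tab <- make_table(list(`9` = c(C = 0.40, G = 0.10, T = 0.25)))
  cls <- classify_tolerance(tab, 9)
  expect_identical(cls$H_base, "C")
  expect_identical(cls$L_base, "G")
  expect_false(cls$tie_H || cls$tie_L)
})

test_that("all-equal rates tie to the alphabetically first base, flagged", {
  tab <- make_table(list(`6` = c(C = 0.2, G = 0.2, T = 0.2)))
  expect_message(cls <- classify_tolerance(tab, 6), "tie")
  expect_identical(cls$H_base, "C")
  expect_identical(cls$L_base, "C")
  expect_true(cls$tie_H && cls$tie_L)
})

test_that("classification matches a brute-force scan and ignores row order", {
  set.seed(41)
  positions <- c(1, 3, 6, 9, 12, 15)
  rates <- lapply(positions, function(p) {
    r <- round(stats::runif(3), 3)
    names(r) <- sample(c("A", "C", "G", "T"), 3)
    r
  })
  names(rates) <- positions
  tab <- make_table(rates)
  cls <- classify_tolerance(tab, positions)
  for (i in seq_along(positions)) {
    r <- rates[[i]]
    ord <- sort(names(r))     # tie order A<C<G<T
    r <- r[ord]
    expect_identical(cls$H_base[i], names(r)[which.max(r)])
    expect_identical(cls$L_base[i], names(r)[which.min(r)])
  }
  shuffled <- tab[sample(nrow(tab)), ]
  cls2 <- classify_tolerance(tolerance_table(shuffled), positions)
  expect_identical(cls[names(cls) != "tie_H"], cls2[names(cls2) != "tie_H"])
  expect_error(classify_tolerance(tab, 20), "position 20")
})

test_that("tolerance tables round-trip through TSV and validate rates", {
  tab <- make_table(list(`3` = c(A = 0.5, C = 0.1, G = 0.3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_tolerance_table(path)
  expect_identical(back$indel_rate, tab$indel_rate)
  expect_error(tolerance_table(data.frame(pam_index = 1, new_base = "A",
                                          indel_rate = 1.2)), "\\[0, 1\\]")
})

test_that("every ARROW guide has 1 mismatch to mutant, 2 to wild-type", {
  for (gene in c("egfr", "kras")) {
    ex <- wex[[gene]]
    guides <- design_arrow_guides(ex$pair, site = ex$site)
    expect_true(all(guides$mm_vs_mut == 1L))
    expect_true(all(guides$mm_vs_wt == 2L))
    # verify independently against the printed protospacers
    wt_proto <- site_sequences(ex$pair$wt_context, ex$site)$protospacer
    expect_identical(wt_proto, ex$wt_guide)
    for (s in guides$sequence) {
      expect_identical(hamming(s, ex$mut_guide), 1L)
      expect_identical(hamming(s, ex$wt_guide), 2L)
    }
  }
})

test_that("an H/L table yields two named guides per position", {
  ex <- wex$egfr
  positions <- default_design_positions(12)
  # synthetic illustrative rates: 3 substitutions per position
  set.seed(57)
  tab <- make_table(stats::setNames(lapply(positions, function(p) {
    base_at <- substr(ex$mut_guide, 21 - p, 21 - p)
    r <- round(stats::runif(3, 0.05, 0.6), 3)
    names(r) <- setdiff(c("A", "C", "G", "T"), base_at)
    r
  }), positions))
  guides <- design_arrow_guides(ex$pair, site = ex$site, positions = positions,
                                table = tab)
  expect_identical(nrow(guides), 12L)   # H and L at each of 6 positions
  expect_identical(sort(unique(guides$label)), c("H", "L"))
  expect_identical(guides$name, paste0("P", guides$pam_index, "-", guides$label))
  expect_true(all(guides$mm_vs_mut == 1L & guides$mm_vs_wt == 2L))
})

test_that("the variant position is forbidden for the intentional mismatch", {
  expect_error(
    design_arrow_guides(wex$egfr$pair, site = wex$egfr$site, positions = c(9, 12)),
    "forbidden")
  expect_error(
    design_arrow_guides(wex$kras$pair, site = wex$kras$site, positions = 1),
    "forbidden")
  # override emits guides but cannot promise the 1-vs-2 contract
  g <- design_arrow_guides(wex$egfr$pair, site = wex$egfr$site, positions = 12,
                           allow_variant_position = TRUE)
  expect_identical(nrow(g), 3L)
})

test_that("design is deterministic and site detection works from the pair", {
  a <- design_arrow_guides(wex$kras$pair, site = wex$kras$site)
  b <- design_arrow_guides(wex$kras$pair, site = wex$kras$site)
  expect_identical(a, b)
  # automatic site detection on a context with a unique covering protospacer
  wt <- paste0("ACATT", "GATTACAGATCAGCATTACA", "TGG", "TCATA")
  mut <- sub("GATCAGC", "GATCTGC", wt)   # A>T inside the protospacer
  pair <- allele_pair(wt, mut)
  auto <- design_arrow_guides(pair, positions = c(1, 3))
  expect_identical(nrow(auto), 6L)
  expect_true(all(auto$mm_vs_mut == 1L & auto$mm_vs_wt == 2L))
  # ambiguous contexts must ask for an explicit site
  expect_error(design_arrow_guides(wex$kras$pair), "candidate protospacers")
})
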