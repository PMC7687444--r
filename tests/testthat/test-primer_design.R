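# Template used throughout: 600 bp, no ambiguity, with a planted diagnostic
# C at position 480 whose 3'-side neighbourhood is fixed to C-A-C so the
# default destabilization rule is exercised exactly as in a real assay.
make_template <- function(seed = 21L, len = 600L, anchor = 480L) {
  withr::with_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    s[anchor:(anchor + 2L)] <- c("C", "A", "C")
    paste(s, collapse = "")
  })
}

test_that("Wallace rule matches hand counts", {
  expect_equal(tm_wallace("ATGC"), 12)
  expect_equal(tm_wallace("GGTTTCGGTCTGTTAATAGTATTTTG"), 70) # 17 AT + 9 GC
  expect_equal(tm_wallace("TATCGTAACCGCACATGCATT"), 60)      # 12 AT + 9 GC
  expect_error(tm_wallace("ACGN"), class = "aspcr_alphabet_error")
})

test_that("nearest-neighbor Tm equals a hand-summed oracle and is symmetric", {
  seq <- "GATCGATCGG"
  # independent summation straight off the shipped parameter table;
  # both terminal bases of this 10-mer are G, hence two GC initiations
  dh <- sum(aspcr:::NN_DH[substring(seq, 1:9, 2:10)]) +
    2 * aspcr:::NN_INIT_DH[["GC"]]
  ds <- sum(aspcr:::NN_DS[substring(seq, 1:9, 2:10)]) +
    2 * aspcr:::NN_INIT_DS[["GC"]] + 0.368 * 9 * log(0.05)
  tm_oracle <- 1000 * dh / (ds + 1.987 * log(0.5e-6 / 4)) - 273.15
  expect_equal(tm_nearest_neighbor(seq), tm_oracle, tolerance = 1e-12)

  withr::with_seed(4, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
      expect_equal(tm_nearest_neighbor(s),
                   tm_nearest_neighbor(reverse_complement(s)))
      expect_gte(tm_nearest_neighbor(paste0(s, "GC")),
                 tm_nearest_neighbor(s))
    }
  })
  expect_error(tm_nearest_neighbor("ACGTACG"), class = "aspcr_config_error")
  expect_error(tm_nearest_neighbor("ACGTACGN"), class = "aspcr_alphabet_error")
})

test_that("gc_content excludes ambiguity from numerator and denominator", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GGTTTCGGTCTGTTAATAGTATTTTG"), 9 / 26)
  expect_equal(gc_content("GCNN"), 1)
  expect_error(gc_content("NNNN"), class = "aspcr_alphabet_error")
})

test_that("perfect_match_primer geometry and anchor complementarity", {
  tmpl <- make_template()
  p <- perfect_match_primer(tmpl, 480L, 26L, "minus")
  expect_equal(c(p$template_start, p$template_end), c(480L, 505L))
  expect_equal(substr(p$seq, 26, 26), "G") # complement of the anchored C
  expect_equal(p$seq, reverse_complement(substr(tmpl, 480, 505)))
  expect_equal(nrow(p$edits), 0L)

  q <- perfect_match_primer(tmpl, 52L, 21L, "plus")
  expect_equal(c(q$template_start, q$template_end), c(32L, 52L))
  expect_equal(q$seq, substr(tmpl, 32, 52))

  # self-consistency with the in silico PCR aligner: zero mismatches
  sites <- find_binding_sites(p, tmpl)
  own <- sites[sites$start == 480L & sites$strand == "minus", ]
  expect_equal(own$n_mismatch, 0L)
  expect_true(own$extendable)

  expect_error(perfect_match_primer(tmpl, 590L, 26L, "minus"),
               class = "aspcr_geometry_error")
  expect_error(perfect_match_primer(tmpl, 10L, 26L, "plus"),
               class = "aspcr_geometry_error")
  gapped <- paste0(substr(tmpl, 1, 482), "-", substr(tmpl, 484, 600))
  expect_error(perfect_match_primer(gapped, 480L, 26L, "minus"),
               class = "aspcr_gap_error")
  expect_error(perfect_match_primer(tmpl, 480L, 12L, "minus"),
               class = "aspcr_config_error")
})

test_that("destabilizing mismatch follows the G->T rule and guards the anchor", {
  tmpl <- make_template()
  p <- perfect_match_primer(tmpl, 480L, 26L, "minus")
  # antepenultimate perfect-match base is G (facing template C at 482)
  expect_equal(substr(p$seq, 24, 24), "G")
  e <- introduce_destabilizing_mismatch(p, tmpl, 3L)
  expect_equal(substr(e$seq, 24, 26), "TTG") # G->T, rest untouched
  expect_equal(e$edits$original_base, "G")
  expect_equal(e$edits$replacement_base, "T")
  expect_equal(e$edits$offset_from_3prime, 3L)

  # exactly one more mismatch than the unedited primer, per the aligner
  model <- binding_model()
  s0 <- find_binding_sites(p, tmpl, model)
  s1 <- find_binding_sites(e, tmpl, model)
  at <- function(df) df[df$start == 480L & df$strand == "minus", ]
  expect_equal(at(s1)$n_mismatch, at(s0)$n_mismatch + 1L)
  expect_equal(at(s1)$mismatch_offsets[[1]], 3L)

  expect_error(introduce_destabilizing_mismatch(p, tmpl, 1L),
               class = "aspcr_config_error")
  expect_error(introduce_destabilizing_mismatch(p, tmpl, 3L, "G"),
               class = "aspcr_config_error")
  expect_error(introduce_destabilizing_mismatch(e, tmpl, 3L),
               class = "aspcr_config_error") # already mismatched
})

test_that("design_allele_specific_primer composes anchor + edit deterministically", {
  tmpl <- make_template()
  site <- list(position = 480L, target_base = "C")
  p1 <- design_allele_specific_primer(tmpl, site)
  p2 <- design_allele_specific_primer(tmpl, site)
  expect_identical(p1$seq, p2$seq)
  expect_equal(substr(p1$seq, 26, 26), "G")
  expect_equal(nrow(p1$edits), 1L)
  expect_equal(p1$edits$offset_from_3prime, 3L)

  bad_site <- list(position = 481L, target_base = "C") # template has A there
  expect_error(design_allele_specific_primer(tmpl, bad_site),
               class = "aspcr_config_error")
})

test_that("companion primers respect every constraint and the ranking rule", {
  tmpl <- make_template()
  asp <- design_allele_specific_primer(tmpl, list(position = 480L,
                                                  target_base = "C"))
  cands <- design_companion_primer(tmpl, asp, product_range = c(400L, 500L))
  expect_gt(length(cands), 0L)
  for (cd in cands) {
    expect_equal(cd$strand, "plus")
    bp <- asp$template_end - cd$template_start + 1L
    expect_true(bp >= 400L && bp <= 500L)
    expect_true(nchar(cd$seq) >= 18L && nchar(cd$seq) <= 25L)
    expect_true(cd$tm_c >= 55 && cd$tm_c <= 65)
    expect_true(cd$gc_frac >= 0.35 && cd$gc_frac <= 0.65)
    expect_lt(cd$template_end, asp$template_start)
  }
  # ranking: first candidate minimizes the Tm gap (full-sort comparison)
  gaps <- vapply(cands, function(cd) abs(cd$tm_c - asp$tm_c), numeric(1))
  expect_equal(gaps, sort(gaps))

  # exhaustive enumeration oracle: same candidate footprints, no omissions
  enum <- list()
  for (len in 18:25) {
    for (s in seq_len(600 - len + 1L)) {
      bp <- asp$template_end - s + 1L
      if (bp < 400L || bp > 500L) next
      if (s + len - 1L >= asp$template_start) next
      sq <- substr(tmpl, s, s + len - 1L)
      gc <- gc_content(sq); tm <- tm_nearest_neighbor(sq)
      if (gc < 0.35 || gc > 0.65 || tm < 55 || tm > 65) next
      last5 <- substr(sq, len - 4L, len)
      rc <- reverse_complement(last5)
      if (grepl(rc, sq, fixed = TRUE) || grepl(rc, asp$seq, fixed = TRUE)) next
      enum[[length(enum) + 1L]] <- c(s, s + len - 1L)
    }
  }
  got <- sort(vapply(cands, function(cd)
    sprintf("%d-%d", cd$template_start, cd$template_end), character(1)))
  want <- sort(vapply(enum, function(e) sprintf("%d-%d", e[1], e[2]),
                      character(1)))
  expect_identical(got, want)

  expect_message(
    empty <- design_companion_primer(tmpl, asp, product_range = c(30L, 40L)),
    "no companion")
  expect_length(empty, 0L)
})

test_that("amplicon geometry follows the footprint-span formula", {
  tmpl <- make_template()
  fwd <- perfect_match_primer(tmpl, 52L, 21L, "plus")
  rev <- design_allele_specific_primer(tmpl, list(position = 480L,
                                                  target_base = "C"))
  expect_equal(amplicon_size(fwd, rev), 474L)
  # size is geometry only: editing the reverse primer does not change it
  pm_rev <- perfect_match_primer(tmpl, 480L, 26L, "minus")
  expect_equal(amplicon_size(fwd, pm_rev), 474L)

  f20 <- perfect_match_primer(tmpl, 20L, 20L, "plus")
  r20 <- perfect_match_primer(tmpl, 1L, 20L, "minus")
  expect_equal(amplicon_size(f20, r20), 20L) # fully overlapping footprints
  expect_error(amplicon_size(rev, fwd), class = "aspcr_config_error")
})

test_that("validate_design passes pipeline output and catches tampering", {
  gen <- generate_alignment(shaped_spec(seed = 13, noise = 0))
  aln <- gen$alignment
  sites <- find_diagnostic_sites(aln, "Cervus_nippon")
  site <- sites[sites$position == 480L, ]
  tmpl <- aln$seq[aln$species == "Cervus_nippon"][1]
  rev <- design_allele_specific_primer(tmpl, site)
  fwd <- design_companion_primer(tmpl, rev)[[1]]
  design <- assay_design(fwd, rev, "Cervus_nippon", site)
  val <- validate_design(design, aln)
  expect_true(attr(val, "overall"))

  broken <- design
  substr(broken$reverse$seq, 26, 26) <- "A"
  v2 <- validate_design(broken, aln)
  expect_false(v2$pass[v2$check == "anchor"])

  tampered <- design
  tampered$product_bp <- tampered$product_bp + 1L
  v3 <- validate_design(tampered, aln)
  expect_false(v3$pass[v3$check == "geometry"])
})
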