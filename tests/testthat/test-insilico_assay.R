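loci <- kdr_loci()

test_that("amplicons are located by unique exact priming", {
  # toy template: 10 bp forward primer, 5 bp spacer, 10 bp reverse site
  fwd <- "ACGTACGTAC"
  rev_site <- "GGATCCGGAT" # as it appears on the template
  template <- paste0("TTTTT", fwd, "CCCCC", rev_site, "AAAAA")
  rev_primer <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  spec <- amplicon_spec("toy", fwd, rev_primer, 25, c(6, 30))
  amp <- find_amplicon(template, spec)
  expect_identical(amp$length, 25L)
  expect_identical(amp$start, 6L)
  expect_identical(amp$sequence, paste0(fwd, "CCCCC", rev_site))

  expect_error(find_amplicon(paste0("TTTTT", fwd, "CCCCC"), spec),
               class = "kdr_amplicon_not_found")
  expect_error(find_amplicon(paste0(template, template), spec),
               class = "kdr_ambiguous_priming")
})

test_that("the kdr amplicon on the synthetic reference is 439 bp", {
  amp <- find_amplicon(ref_fixture$sequence, ref_fixture$kdr_amplicon)
  expect_identical(amp$length, 439L)
  skdr <- find_amplicon(ref_fixture$sequence, ref_fixture$skdr_amplicon)
  expect_identical(skdr$length, 151L)
})

test_that("IUPAC codes in the template still prime exactly", {
  s <- ref_fixture$sequence
  # heterozygous variant inside the amplicon must not break priming
  substr(s, 3070, 3070) <- "Y"
  amp <- find_amplicon(s, ref_fixture$kdr_amplicon)
  expect_identical(amp$length, 439L)
})

test_that("RFLP digestion reproduces the diagnostic band patterns", {
  amp_wt <- find_amplicon(ref_fixture$sequence, ref_fixture$kdr_amplicon)$sequence
  amp_mut <- amp_wt
  substr(amp_mut, 160, 160) <- "T" # variant base at amplicon offset 160

  sus <- digest(amp_wt, ref_fixture$enzyme, loci[["1014"]])
  expect_identical(sus$bands, c(154L, 285L))
  expect_identical(format(sus$call), "L/L")

  res <- digest(amp_mut, ref_fixture$enzyme, loci[["1014"]])
  expect_identical(res$bands, 439L)
  expect_identical(format(res$call), "F/F")

  het <- digest(c(amp_wt, amp_mut), ref_fixture$enzyme, loci[["1014"]])
  expect_identical(het$bands, c(154L, 285L, 439L))
  expect_identical(format(het$call), "L/F")

  expect_error(digest(character(0), ref_fixture$enzyme), class = "kdr_no_template")
})

test_that("digest fragment lengths sum to the allele length on random sequences", {
  set.seed(7)
  enz <- ref_fixture$enzyme
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    # salt some sites in to exercise multi-cut digests
    if (i %% 3 == 0) {
      at <- sample(1:280, 2)
      for (p in at) substr(s, p, p + 6) <- "GGTCACC"
    }
    res <- digest(s, enz)
    for (fr in res$fragments_per_allele) expect_identical(sum(fr), 300L)
  }
})

test_that("BstEII site recognition is palindromic and duplex cuts mirror exactly", {
  # GGTNACC is its own reverse complement, so the same physical sites are seen
  # from either strand; the staggered G^GTNACC cut leaves a 5-base 5' overhang,
  # so the bottom-strand (reverse-complement) cut of each site sits exactly 5
  # bases 3' of the top-strand cut.
  set.seed(11)
  enz <- ref_fixture$enzyme
  overhang <- nchar(enz$recognition) - 2L * enz$cut_offset
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE), collapse = "")
    at <- sample(1:240, 1)
    substr(s, at, at + 6) <- sample(c("GGTAACC", "GGTCACC", "GGTGACC", "GGTTACC"), 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f_top <- digest(s, enz)$fragments_per_allele[[1]]
    f_rc <- digest(rc, enz)$fragments_per_allele[[1]]
    expect_identical(length(f_top), length(f_rc))      # same number of sites
    expect_identical(sum(f_top), sum(f_rc))            # conservation both ways
    cuts_top <- head(cumsum(f_top), -1L)
    cuts_rc_mapped <- sort(nchar(s) - head(cumsum(f_rc), -1L))
    expect_identical(cuts_rc_mapped, cuts_top + overhang)
  }
})

test_that("LCR products map to the diagnostic genotype calls", {
  ref <- ref_fixture
  amp_wt <- find_amplicon(ref$sequence, ref$skdr_amplicon)$sequence
  amp_mut <- amp_wt
  substr(amp_mut, 59, 59) <- "A" # 2784 at amplicon offset 2784-2726+1 = 59

  mm <- lcr_genotype(amp_wt, ref$probes, loci[["918"]])
  expect_identical(mm$bands, 141L)
  expect_identical(format(mm$call), "M/M")

  het <- lcr_genotype(c(amp_wt, amp_mut), ref$probes, loci[["918"]])
  expect_identical(het$bands, c(141L, 165L))
  expect_identical(format(het$call), "M/I")

  ii <- lcr_genotype(amp_mut, ref$probes, loci[["918"]])
  expect_identical(ii$bands, 165L)
  expect_identical(format(ii$call), "I/I")

  # a template missing the P2 annealing site fails the assay
  broken <- paste(rep("A", 151), collapse = "")
  expect_error(lcr_genotype(broken, ref$probes, loci[["918"]]),
               class = "kdr_assay_failure")
})

test_that("direct codon calls work on anchored consensus sequences", {
  ref <- ref_fixture
  s <- ref$sequence
  expect_identical(format(call_codon_variant(s, loci[["1014"]], ref$sequence)), "L/L")
  substr(s, 3070, 3070) <- "Y"
  expect_identical(format(call_codon_variant(s, loci[["1014"]], ref$sequence)), "L/F")
  substr(s, 2784, 2784) <- "R"
  expect_identical(format(call_codon_variant(s, loci[["918"]], ref$sequence)), "M/I")
  substr(s, 3070, 3070) <- "T"
  expect_identical(format(call_codon_variant(s, loci[["1014"]], ref$sequence)), "F/F")
  expect_error(call_codon_variant(substr(ref$sequence, 1, 500), loci[["1014"]],
                                  ref$sequence),
               class = "kdr_coverage_error")
})

test_that("all three assay routes agree with ground truth for all nine classes", {
  seqs <- render_sequences(designed_cohort, ref_fixture, noise_rate = 0)
  for (i in seq_len(nrow(designed_cohort))) {
    g <- genotype_sample(seqs[[i]], ref_fixture)
    expect_identical(g$string, designed_cohort$genotype[i])
    prov <- attr(g, "provenance")
    expect_setequal(prov$method, c("RFLP", "LCR", "codon"))
  }
})

test_that("corrupting the restriction site only triggers a discordance error", {
  ind <- designed_cohort[designed_cohort$genotype == "L/L:M/M", ][1, ]
  s <- render_sequences(ind, ref_fixture)[[1]]
  substr(s, 3068, 3068) <- "G" # destroy GGTNACC without touching the 1014 codon
  expect_error(genotype_sample(s, ref_fixture), class = "kdr_discordance")
})

test_that("an ambiguity code away from assay positions never changes a call", {
  ind <- designed_cohort[designed_cohort$genotype == "L/F:M/I", ][1, ]
  s0 <- render_sequences(ind, ref_fixture)[[1]]
  free <- setdiff(seq_len(nchar(s0)), ref_fixture$protected)
  set.seed(5)
  for (pos in sample(free, 10)) {
    s <- s0
    substr(s, pos, pos) <- "N"
    # N positions inflate the expansion budget; allow for the extra site
    g <- genotype_sample(s, ref_fixture, max_het_sites = 4)
    expect_identical(g$string, "L/F:M/I")
  }
})
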