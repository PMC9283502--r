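test_that("the synthetic reference is deterministic and assay-consistent", {
  ref2 <- make_reference(seed = 1L)
  expect_identical(ref2$sequence, ref_fixture$sequence)
  expect_false(identical(make_reference(seed = 2L)$sequence, ref_fixture$sequence))

  s <- ref_fixture$sequence
  expect_identical(nchar(s), 3525L)
  expect_identical(substr(s, 3070, 3072), "CTT") # wild-type leucine codon
  expect_identical(substr(s, 2782, 2784), "ATG") # wild-type methionine codon
  # exactly one BstEII site on the whole transcript, at the kdr codon
  hits <- gregexpr("GGT[ACGT]ACC", s)[[1]]
  expect_identical(as.integer(hits), 3064L)
  # wild-type digest reproduces the diagnostic fragments
  amp <- find_amplicon(s, ref_fixture$kdr_amplicon)$sequence
  expect_identical(digest(amp, ref_fixture$enzyme)$bands, c(154L, 285L))
  expect_identical(ref_fixture$probes$wt_product_len, 141L)
  expect_identical(ref_fixture$probes$mut_product_len, 165L)
})

test_that("cohort draws follow the haplotype frequencies", {
  fixed <- sample_population(c(1, 0, 0, 0), n = 50, seed = 2)
  expect_true(all(fixed$genotype == "L/L:M/M"))

  expect_identical(sample_population(n = 100, seed = 7),
                   sample_population(n = 100, seed = 7))

  # per-locus heterozygote fraction ~ 2p(1-p) within 3 SE at large n
  n <- 10000
  pop <- sample_population(n = n, seed = 11)
  p_f <- DEFAULT_HAPLOTYPE_FREQS[["FM"]] + DEFAULT_HAPLOTYPE_FREQS[["FI"]]
  het_expected <- 2 * p_f * (1 - p_f)
  het_obs <- mean(substr(pop$hap1, 1, 1) != substr(pop$hap2, 1, 1))
  se <- sqrt(het_expected * (1 - het_expected) / n)
  expect_lt(abs(het_obs - het_expected), 3 * se)
})

test_that("rendered consensus sequences carry the genotype and nothing else at noise 0", {
  ind <- designed_cohort[designed_cohort$genotype == "F/F:M/I", ][1, ]
  s <- render_sequences(ind, ref_fixture, noise_rate = 0)[[1]]
  expect_identical(substr(s, 3070, 3070), "T")
  expect_identical(substr(s, 2784, 2784), "R")
  # identical to the reference away from the two variant positions
  mism <- which(strsplit(s, "")[[1]] != strsplit(ref_fixture$sequence, "")[[1]])
  expect_identical(mism, c(2784L, 3070L))
})

test_that("noise stays off assay-critical positions and the round trip still calls", {
  pop <- sample_population(n = 12, seed = 3)
  seqs <- render_sequences(pop, ref_fixture, noise_rate = 0.002, seed = 3)
  ref_chars <- strsplit(ref_fixture$sequence, "")[[1]]
  touched <- unique(unlist(lapply(seqs, function(s) {
    which(strsplit(s, "")[[1]] != ref_chars)
  })))
  var_pos <- c(2784L, 3070L)
  expect_length(intersect(setdiff(touched, var_pos), ref_fixture$protected), 0)
})

test_that("selection enriches resistant classes and is calibrated under the null", {
  pop <- sample_population(n = 2000, seed = 17)
  pre <- tally_genotypes(pop)

  sel <- apply_selection(pop, seed = 17)
  expect_identical(nrow(sel$survivors) + nrow(sel$moribund), nrow(pop))
  post <- tally_genotypes(sel$survivors)
  for (locus in c("1014", "918")) {
    expect_gt(raf(post, locus), raf(pre, locus))
  }

  all_live <- apply_selection(pop, survival = setNames(rep(1, 6), names(DEFAULT_SELECTION)))
  expect_identical(nrow(all_live$moribund), 0L)

  # equal survival leaves expected RAF unchanged (within 3 SE of binomial noise)
  flat <- apply_selection(pop, survival = setNames(rep(0.5, 6), names(DEFAULT_SELECTION)),
                          seed = 23)
  n_surv <- nrow(flat$survivors)
  p <- raf(pre, "1014") / 100
  se <- sqrt(p * (1 - p) / (2 * n_surv))
  expect_lt(abs(raf(tally_genotypes(flat$survivors), "1014") / 100 - p), 3 * se)
})

test_that("post-selection class frequencies converge to f*s / sum(f*s)", {
  pop <- sample_population(n = 1e5, seed = 29)
  sel <- apply_selection(pop, seed = 29)
  f <- table(factor(pop$class, names(DEFAULT_SELECTION))) / nrow(pop)
  w <- f * DEFAULT_SELECTION
  expected <- as.numeric(w / sum(w))
  obs_tab <- table(factor(sel$survivors$class, names(DEFAULT_SELECTION)))
  obs <- as.numeric(obs_tab) / nrow(sel$survivors)
  se <- sqrt(expected * (1 - expected) / nrow(sel$survivors))
  expect_true(all(abs(obs - expected) <= 3 * se + 1e-12))
})

test_that("simulated bioassays follow the LL.3 law", {
  rec <- simulate_bioassay(b = 2.5, d = 1, e = 0.38, seed = 31)
  expect_identical(nrow(rec), 9L) # 8 doses + control
  expect_true(all(rec$dead <= rec$n))
  # huge dose with d = 1 kills everything
  lethal <- simulate_bioassay(b = 3, d = 1, e = 0.1, doses = c(1, 10, 1e5),
                              n_per_dose = 100L, control_n = 0L, seed = 33)
  expect_identical(lethal$dead[lethal$dose == 1e5], 100L)
  # dose-0 control row dies at about the control rate, not the curve
  many <- simulate_bioassay(seed = 37, control_n = 5000L, control_mortality = 0.02)
  expect_lt(many$dead[many$dose == 0] / 5000, 0.04)
})

test_that("RR-structured populations recover the generating resistance ratio", {
  sus <- fit_ll3(simulate_bioassay(b = 2.5, d = 1, e = 0.38, n_per_dose = 180L, seed = 41))
  res <- fit_ll3(simulate_bioassay(b = 2.1, d = 1, e = 18.33, n_per_dose = 180L, seed = 43))
  rr <- ratio(res, sus, "RR")
  expect_equal(rr$ratio, 48.2, tolerance = 0.2)
  expect_true(rr$significant)
})
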