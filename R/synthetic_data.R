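# Synthetic-data generator: a deterministic reference transcript carrying the
# wild-type kdr/super-kdr codons with working assay geometry, diploid cohorts
# drawn from four haplotype frequencies, IUPAC consensus rendering, selection
# experiments, and binomial bioassay tables under the LL.3 law.

# run code with a private RNG stream derived from (seed, stream name) so the
# caller's RNG state is untouched and stages are independently reproducible
with_substream <- function(seed, stream, code) {
  # derive the substream seed first: `seed` may be a lazy expression that
  # itself consumes the caller's RNG, and must do so before the state is saved
  sub <- as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(stream)) * 97) %%
                      2147483646) + 1L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub)
  force(code)
}

#' The four two-locus haplotypes
#' @export
HAPLOTYPES <- c("LM", "LI", "FM", "FI")

#' Default field haplotype frequencies
#'
#' Order `LM, LI, FM, FI` (1014 allele then 918 allele). The defaults mirror a
#' mostly wild-type/kdr-heterozygous field spectrum in which the 918I allele
#' rides almost exclusively on 1014F haplotypes.
#' @export
DEFAULT_HAPLOTYPE_FREQS <- c(LM = 0.55, LI = 0.05, FM = 0.30, FI = 0.10)

#' Default per-genotype-class survival at a field application
#'
#' Survival probabilities increase with resistance class.
#' @export
DEFAULT_SELECTION <- c(
  "wild type" = 0.05, "918-only" = 0.05,
  "kdr heterozygote" = 0.50, "kdr homozygote" = 0.60,
  "super-kdr heterozygote" = 0.90, "super-kdr homozygote" = 0.95
)

#' Generate the synthetic vgsc reference transcript and assay definitions
#'
#' Emits a deterministic 3,525 bp transcript (30 bp 5' UTR then CDS) carrying
#' wild-type codons CTT at aa 1014 (variant base transcript position 3070,
#' first codon base) and ATG at aa 918 (variant 2784, third base). The kdr
#' amplicon is 439 bp with exactly one BstEII site (GGTNACC at 3064-3070, the
#' terminal C being the L1014F variant base) placed so that G^GTNACC digestion
#' of the wild-type amplicon yields fragments of 154 and 285 bp. The
#' super-kdr (LCR) amplicon is 151 bp around position 2784; LCR probes give
#' 141 bp (wild type) and 165 bp (mutant, 24-base 5' extension) products.
#'
#' @param seed integer seed; the same seed always yields the same bundle.
#' @return list: `sequence`, `loci` (see [kdr_loci()]), `kdr_amplicon`,
#'   `skdr_amplicon` ([amplicon_spec()]s), `enzyme`, `probes`, `seed`,
#'   `protected` (assay-critical transcript positions).
#' @export
make_reference <- function(seed = 1L) {
  len <- 3525L
  loci <- kdr_loci()
  seq_chars <- with_substream(seed, "reference", {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })

  put <- function(chars, at, what) {
    chars[at:(at + nchar(what) - 1L)] <- strsplit(what, "")[[1]]
    chars
  }
  # wild-type codons: aa 918 codon at 2782 (ATG), aa 1014 codon at 3070 (CTT);
  # BstEII site GGTAACC at 3064-3070 (codon 1012 = GGT, 1013 = AAC, then C of CTT)
  seq_chars <- put(seq_chars, 2782L, "ATG")
  seq_chars <- put(seq_chars, 3064L, "GGTAACC")
  seq_chars <- put(seq_chars, 3070L, "CTT")

  # scrub every other (possibly chance) BstEII site so the kdr amplicon - and
  # the transcript - carries exactly one
  repeat {
    s <- paste(seq_chars, collapse = "")
    hits <- gregexpr("GGT[ACGT]ACC", s)[[1]]
    hits <- hits[hits > 0 & hits != 3064L]
    if (!length(hits)) break
    seq_chars[hits[1L]] <- "C" # destroy the first G of the stray site
  }
  sequence <- paste(seq_chars, collapse = "")

  # amplicon geometry (1-based inclusive transcript coordinates):
  # kdr amplicon 2911-3349 (439 bp; cut after amplicon position 154 -> 154+285)
  kdr_iv <- c(2911L, 3349L)
  skdr_iv <- c(2726L, 2876L) # 151 bp around the 918 variant at 2784
  sub <- function(iv) substr(sequence, iv[1L], iv[2L])
  kdr_amp <- amplicon_spec(
    "kdr-DIIS6", substr(sequence, 2911L, 2930L),
    revcomp(substr(sequence, 3330L, 3349L)), 439L, kdr_iv
  )
  skdr_amp <- amplicon_spec(
    "skdr-M918I", substr(sequence, 2726L, 2745L),
    revcomp(substr(sequence, 2857L, 2876L)), 151L, skdr_iv
  )
  enzyme <- enzyme_spec("BstEII", "GGTNACC", 1L)

  # LCR probes: P1 core = 25 bp ending at the variant base 2784; the mutant P1
  # carries a fixed 24-base 5' extension and ends in A. P2 = 81 bp from 2785.
  p1_core <- substr(sequence, 2760L, 2784L)
  p1_mut <- paste0("ACGTACGTACGTACGTACGTACGT",
                   substr(p1_core, 1L, 24L), loci[["918"]]$mut_base)
  probes <- lcr_probe_set(p1_wt = p1_core, p1_mut = p1_mut,
                          p2_phos = substr(sequence, 2785L, 2865L))
  stopifnot(probes$wt_product_len == 141L, probes$mut_product_len == 165L)

  ref <- list(
    sequence = sequence, loci = loci, kdr_amplicon = kdr_amp,
    skdr_amplicon = skdr_amp, enzyme = enzyme, probes = probes, seed = seed,
    protected = unique(c(2726:2745, 2857:2876, 2911:2930, 3330:3349, # primers
                         2760:2865,                                  # LCR probes
                         3064:3072, 2782:2784))                      # site+codons
  )
  # validate the assay geometry once per construction
  for (spec in list(kdr_amp, skdr_amp)) {
    amp <- find_amplicon(sequence, spec)
    stopifnot(amp$length == spec$expected_length,
              amp$start == spec$reference_interval[1L],
              amp$end == spec$reference_interval[2L])
  }
  wt_dig <- digest(find_amplicon(sequence, kdr_amp)$sequence, enzyme)
  stopifnot(identical(wt_dig$bands, c(154L, 285L)))
  ref
}

#' Draw a diploid cohort from haplotype frequencies
#'
#' Each individual is the union of two independently drawn gametes (random
#' mating over haplotypes; linkage disequilibrium is controlled entirely by
#' the haplotype frequencies).
#'
#' @param freqs frequencies of the `LM, LI, FM, FI` haplotypes (sum 1).
#' @param n cohort size.
#' @param seed integer seed (substream `"population"`).
#' @param loci list from [kdr_loci()].
#' @return data.frame: `sample_id`, `hap1`, `hap2`, `genotype` (nine-class
#'   string), `class` (resistance-class label).
#' @export
sample_population <- function(freqs = DEFAULT_HAPLOTYPE_FREQS, n, seed = 1L,
                              loci = kdr_loci()) {
  stopifnot(length(freqs) == 4L, all(freqs >= 0), abs(sum(freqs) - 1) < 1e-8)
  names(freqs) <- HAPLOTYPES
  haps <- with_substream(seed, "population", {
    matrix(sample(HAPLOTYPES, 2L * n, replace = TRUE, prob = freqs), ncol = 2L)
  })
  geno <- apply(haps, 1L, function(h) {
    g <- classify_genotype(
      diploid_call(loci[["1014"]], substr(h, 1L, 1L)),
      diploid_call(loci[["918"]], substr(h, 2L, 2L))
    )
    c(g$string, g$class_label)
  })
  data.frame(
    sample_id = sprintf("ind%05d", seq_len(n)),
    hap1 = haps[, 1L], hap2 = haps[, 2L],
    genotype = geno[1L, ], class = geno[2L, ],
    stringsAsFactors = FALSE
  )
}

#' Render per-individual IUPAC consensus sequences
#'
#' Writes each individual's two-locus genotype into a copy of the reference:
#' heterozygous sites become IUPAC codes (Y at 3070, R at 2784). Optional
#' uniform substitution noise is applied away from assay-critical positions
#' (primers, probes, restriction site, the two codons).
#'
#' @param individuals data.frame from [sample_population()].
#' @param reference bundle from [make_reference()].
#' @param noise_rate per-base substitution probability outside protected
#'   positions (default 0).
#' @param seed integer seed (substream `"noise"`).
#' @return named character vector of sequences (names = sample ids).
#' @export
render_sequences <- function(individuals, reference, noise_rate = 0, seed = 1L) {
  loci <- reference$loci
  base_at <- function(aa1, aa2, locus) {
    b <- ifelse(c(aa1, aa2) == locus$mut_aa, locus$mut_base, locus$wt_base)
    if (b[1L] == b[2L]) b[1L] else {
      # IUPAC code for the unordered base pair
      pair <- paste(sort(b), collapse = "")
      names(IUPAC_CODES)[match(pair, IUPAC_CODES)]
    }
  }
  seqs <- with_substream(seed, "noise", {
    vapply(seq_len(nrow(individuals)), function(i) {
      chars <- strsplit(reference$sequence, "")[[1]]
      a1014 <- substr(c(individuals$hap1[i], individuals$hap2[i]), 1L, 1L)
      a918 <- substr(c(individuals$hap1[i], individuals$hap2[i]), 2L, 2L)
      chars[loci[["1014"]]$transcript_position] <-
        base_at(a1014[1L], a1014[2L], loci[["1014"]])
      chars[loci[["918"]]$transcript_position] <-
        base_at(a918[1L], a918[2L], loci[["918"]])
      if (noise_rate > 0) {
        free <- setdiff(seq_along(chars), reference$protected)
        hit <- free[stats::runif(length(free)) < noise_rate]
        if (length(hit)) {
          chars[hit] <- vapply(chars[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
      }
      paste(chars, collapse = "")
    }, character(1))
  })
  names(seqs) <- individuals$sample_id
  seqs
}

#' Apply genotype-class-dependent selection to a cohort
#'
#' Bernoulli survival per individual with probability given by its resistance
#' class; both groups keep their ground truth.
#'
#' @param individuals data.frame from [sample_population()].
#' @param survival named vector of survival probabilities per class label
#'   (default [DEFAULT_SELECTION]).
#' @param seed integer seed (substream `"selection"`).
#' @return list with `survivors` and `moribund` data.frames.
#' @export
apply_selection <- function(individuals, survival = DEFAULT_SELECTION, seed = 1L) {
  miss <- setdiff(unique(individuals$class), names(survival))
  if (length(miss)) {
    stop_kdr(paste("no survival probability for class(es):",
                   paste(miss, collapse = ", ")), "kdr_invalid_selection")
  }
  p <- unname(survival[individuals$class])
  stopifnot(all(p >= 0 & p <= 1))
  alive <- with_substream(seed, "selection", {
    stats::runif(nrow(individuals)) < p
  })
  list(survivors = individuals[alive, , drop = FALSE],
       moribund = individuals[!alive, , drop = FALSE])
}

#' Tally a cohort into a genotype count table
#'
#' @param individuals data.frame with a `genotype` column of nine-class strings.
#' @param location,year,group stratum labels.
#' @return a [genotype_count_table()].
#' @export
tally_genotypes <- function(individuals, location = "synthetic", year = NA,
                            group = "sample") {
  counts <- table(factor(individuals$genotype, levels = GENOTYPE_CLASSES_9))
  genotype_count_table(location, year, group, setNames(as.integer(counts),
                                                       GENOTYPE_CLASSES_9))
}

#' Simulate a dose-mortality bioassay under the LL.3 law
#'
#' Binomial deaths at `p(x) = d / (1 + (x/e)^(-b))` per concentration; dose-0
#' control rows die at `control_mortality`.
#'
#' @param b,d,e generating LL.3 parameters (slope, upper limit, LC50).
#' @param doses positive concentrations (default 8 points log-spaced over the
#'   0.0008-60 ug/ml assay range).
#' @param n_per_dose aphids per concentration (default 60 = 3 reps x 20).
#' @param control_n,control_mortality optional dose-0 row.
#' @param population label column.
#' @param seed integer seed (substream `"bioassay"`).
#' @return data.frame of bioassay records: `population`, `dose`, `n`, `dead`.
#' @export
simulate_bioassay <- function(b = 2.5, d = 1, e = 0.38,
                              doses = exp(seq(log(0.0008), log(60), length.out = 8)),
                              n_per_dose = 60L, control_n = 60L,
                              control_mortality = 0.02,
                              population = "synthetic", seed = 1L) {
  stopifnot(all(doses > 0), b > 0, d > 0, d <= 1, e > 0)
  p <- ll3_p(doses, b, d, e)
  with_substream(seed, "bioassay", {
    dead <- stats::rbinom(length(doses), n_per_dose, p)
    rows <- data.frame(population = population, dose = doses,
                       n = n_per_dose, dead = dead, stringsAsFactors = FALSE)
    if (!is.null(control_n) && control_n > 0L) {
      rows <- rbind(
        data.frame(population = population, dose = 0, n = control_n,
                   dead = stats::rbinom(1L, control_n, control_mortality),
                   stringsAsFactors = FALSE),
        rows
      )
    }
    rows
  })
}
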