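# In-silico genotyping assays: PCR amplicon location, allele expansion from
# IUPAC consensus, BstEII restriction digest (RFLP), allele-specific ligation
# (LCR), and direct codon calling against a reference transcript.

# IUPAC-aware single-occurrence pattern search. `fixed = FALSE` lets ambiguity
# codes in either string match on base-set intersection, which for a concrete
# primer equals "primer base is among the template code's expansion".
iupac_match_positions <- function(pattern, subject) {
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    fixed = FALSE
  )
  cbind(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define a PCR amplicon
#'
#' @param name amplicon label.
#' @param forward_primer,reverse_primer primer sequences over `A/C/G/T`; the
#'   reverse primer is given 5'->3' on the opposite strand as usual.
#' @param expected_length expected product length in bp.
#' @param reference_interval 1-based inclusive transcript coordinates of the
#'   product on the reference (informational).
#' @return object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, forward_primer, reverse_primer, expected_length,
                          reference_interval) {
  stopifnot(
    grepl("^[ACGT]+$", forward_primer), grepl("^[ACGT]+$", reverse_primer),
    expected_length > nchar(forward_primer) + nchar(reverse_primer),
    length(reference_interval) == 2L
  )
  structure(
    list(
      name = name, forward_primer = toupper(forward_primer),
      reverse_primer = toupper(reverse_primer),
      expected_length = as.integer(expected_length),
      reference_interval = as.integer(reference_interval)
    ),
    class = "amplicon_spec"
  )
}

#' Define a restriction enzyme
#'
#' Defaults to BstEII: degenerate palindromic recognition `GGTNACC`, cutting
#' the top strand after the first base (`G^GTNACC`).
#'
#' @param name enzyme name.
#' @param recognition degenerate IUPAC recognition site; must be its own
#'   reverse complement under IUPAC matching.
#' @param cut_offset bases after the site start at which the top strand is cut
#'   (strictly inside the site).
#' @return object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name = "BstEII", recognition = "GGTNACC", cut_offset = 1L) {
  recognition <- toupper(recognition)
  stopifnot(cut_offset > 0L, cut_offset < nchar(recognition))
  if (!identical(revcomp(recognition), recognition)) {
    stop_kdr("recognition site must be palindromic under IUPAC complement",
             "kdr_invalid_enzyme")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = as.integer(cut_offset)),
    class = "enzyme_spec"
  )
}

#' Define an LCR probe set for a biallelic SNP
#'
#' The two upstream P1 probes are allele-specific through their 3'-terminal
#' base (wild type vs mutant variant nucleotide); the mutant P1 carries a 5'
#' extension so the two ligation products are size-distinguishable. P2 is the
#' common 5'-phosphorylated downstream probe annealing immediately 3' of the
#' variant. Amplification of ligation products with outer tail primers adds
#' `tail_f_len + tail_r_len` bases.
#'
#' @param p1_wt,p1_mut allele-specific upstream probes (genomic 3' ends).
#' @param p2_phos downstream probe.
#' @param tail_f_len,tail_r_len outer tail primer lengths added on PCR.
#' @return object of class `lcr_probe_set` with computed `wt_product_len` and
#'   `mut_product_len`.
#' @export
lcr_probe_set <- function(p1_wt, p1_mut, p2_phos, tail_f_len = 17L, tail_r_len = 18L) {
  probes <- structure(
    list(
      p1_wt = toupper(p1_wt), p1_mut = toupper(p1_mut), p2_phos = toupper(p2_phos),
      tail_f_len = as.integer(tail_f_len), tail_r_len = as.integer(tail_r_len)
    ),
    class = "lcr_probe_set"
  )
  probes$wt_product_len <- tail_f_len + nchar(p1_wt) + nchar(p2_phos) + tail_r_len
  probes$mut_product_len <- tail_f_len + nchar(p1_mut) + nchar(p2_phos) + tail_r_len
  probes
}

#' Locate a PCR amplicon on a template
#'
#' Finds the unique interval starting at the forward-primer match and ending
#' at the reverse complement of the reverse primer. Primer matching is exact
#' (no mismatches), but IUPAC codes in the template match a concrete primer
#' base when that base is among the code's expansion.
#'
#' @param template IUPAC nucleotide string.
#' @param spec an [amplicon_spec()].
#' @return list with `sequence`, `start`, `end` (1-based inclusive on the
#'   template) and `length`.
#' @export
find_amplicon <- function(template, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  fwd <- iupac_match_positions(spec$forward_primer, template)
  rev <- iupac_match_positions(revcomp(spec$reverse_primer), template)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    stop_kdr(
      sprintf("amplicon '%s' not found: %s primer has no match", spec$name,
              if (nrow(fwd) == 0L) "forward" else "reverse"),
      "kdr_amplicon_not_found"
    )
  }
  if (nrow(fwd) > 1L || nrow(rev) > 1L) {
    stop_kdr(
      sprintf("ambiguous priming for amplicon '%s' (multiple primer matches)", spec$name),
      "kdr_ambiguous_priming"
    )
  }
  start <- fwd[1L, "start"]
  end <- rev[1L, "end"]
  if (end <= start) {
    stop_kdr(sprintf("amplicon '%s' primers in wrong orientation", spec$name),
             "kdr_amplicon_not_found")
  }
  list(
    sequence = substr(template, start, end),
    start = unname(start), end = unname(end), length = unname(end - start + 1L)
  )
}

#' Expand a consensus amplicon into its constituent allele sequences
#'
#' Heterozygous positions in a Sanger consensus appear as IUPAC codes
#' (co-occurring peaks); this expands them into concrete allele sequences.
#'
#' @param amplicon IUPAC sequence.
#' @param max_het_sites maximum ambiguous positions tolerated (default 2);
#'   beyond this the trace is considered unusable.
#' @return character vector of concrete sequences.
#' @export
expand_alleles <- function(amplicon, max_het_sites = 2L) {
  expand_iupac(amplicon, max_sites = max_het_sites)
}

# collapse per-expansion amino acids into an unordered diploid allele pair;
# more than two expansions can arise from incidental ambiguity codes, but they
# must reduce to at most two distinct alleles
pair_from_aas <- function(aas, locus, assay) {
  u <- unique(aas)
  if (length(u) > 2L) {
    stop_kdr(
      sprintf("%s assay: expansions imply %d distinct alleles at %s", assay,
              length(u), locus$name),
      "kdr_assay_failure"
    )
  }
  if (length(u) == 1L) rep(u, 2L) else u
}

has_cut_site <- function(seq, enzyme) {
  nrow(iupac_match_positions(enzyme$recognition, seq)) > 0L
}

digest_one <- function(seq, enzyme) {
  hits <- iupac_match_positions(enzyme$recognition, seq)
  if (nrow(hits) == 0L) return(nchar(seq))
  cuts <- sort(unname(hits[, "start"]) + enzyme$cut_offset - 1L) # cut after this base
  bounds <- c(0L, cuts, nchar(seq))
  unname(diff(bounds))
}

#' Simulate an RFLP restriction digest and call the genotype
#'
#' Each allele sequence is scanned on the top strand for IUPAC matches of the
#' recognition site and cut at the enzyme's offset; the band pattern is the
#' union of fragment sizes over alleles. When `locus` is supplied, each allele
#' is called wild type if it carries a cut site (the susceptible allele
#' retains the site) and mutant otherwise, giving the diploid call.
#'
#' @param allele_sequences character vector of 1-2 concrete allele sequences
#'   (e.g. from [expand_alleles()]).
#' @param enzyme an [enzyme_spec()].
#' @param locus optional `resistance_locus` used to label the call.
#' @return list of class `assay_result`: `assay = "RFLP"`, `bands` (sorted
#'   unique bp), `fragments_per_allele`, and `call` (a `diploid_call` or NULL).
#' @export
digest <- function(allele_sequences, enzyme, locus = NULL) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (length(allele_sequences) == 0L) {
    stop_kdr("no template sequences supplied to digest", "kdr_no_template")
  }
  frags <- lapply(allele_sequences, digest_one, enzyme = enzyme)
  call <- NULL
  if (!is.null(locus)) {
    allele_aas <- vapply(
      allele_sequences,
      function(s) if (has_cut_site(s, enzyme)) locus$wt_aa else locus$mut_aa,
      character(1)
    )
    call <- diploid_call(locus, pair_from_aas(unname(allele_aas), locus, "RFLP"))
  }
  structure(
    list(
      assay = "RFLP", bands = sort(unique(unlist(frags))),
      fragments_per_allele = frags, call = call
    ),
    class = "assay_result"
  )
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %s bands {%s}%s\n", x$assay,
              paste(x$bands, collapse = ", "),
              if (!is.null(x$call)) paste0(" call ", format(x$call)) else ""))
  invisible(x)
}

# Ligation rule for one concrete allele: P2 must anneal (exact, unique match);
# a P1 ligates iff its genomic 3'-terminal base equals the allele base
# immediately 5' of the P2 site and the rest of its genomic footprint matches.
lcr_one <- function(seq, probes) {
  p2 <- iupac_match_positions(probes$p2_phos, seq)
  if (nrow(p2) != 1L) return(character(0))
  var_pos <- p2[1L, "start"] - 1L
  ligates <- function(p1) {
    # strip any non-genomic 5' extension by matching the longest suffix of p1
    # that ends exactly at var_pos
    k <- min(nchar(p1), var_pos)
    suffix <- substr(p1, nchar(p1) - k + 1L, nchar(p1))
    target <- substr(seq, var_pos - k + 1L, var_pos)
    # require at least the allele-specific terminal base plus a 10 bp anchor
    while (k > 10L && suffix != target) {
      k <- k - 1L
      suffix <- substr(suffix, 2L, nchar(suffix))
      target <- substr(seq, var_pos - k + 1L, var_pos)
    }
    k > 10L && suffix == target
  }
  out <- character(0)
  if (ligates(probes$p1_wt)) out <- c(out, "wt")
  if (ligates(probes$p1_mut)) out <- c(out, "mut")
  out
}

#' Simulate an LCR (ligase chain reaction) genotyping assay
#'
#' For each allele, an allele-specific P1 probe ligates to the common P2 probe
#' only when its 3'-terminal base matches the allele's variant nucleotide;
#' ligation products are then amplified with outer tail primers to
#' size-distinguishable products (wild type vs mutant, e.g. 141 vs 165 bp).
#'
#' @param allele_sequences concrete allele sequences.
#' @param probes an [lcr_probe_set()].
#' @param locus optional `resistance_locus` used to label the call.
#' @return `assay_result` with `assay = "LCR"`, `bands` the product sizes, and
#'   `call` the implied diploid call.
#' @export
lcr_genotype <- function(allele_sequences, probes, locus = NULL) {
  stopifnot(inherits(probes, "lcr_probe_set"))
  if (length(allele_sequences) == 0L) {
    stop_kdr("no template sequences supplied to LCR", "kdr_no_template")
  }
  per_allele <- lapply(allele_sequences, lcr_one, probes = probes)
  if (all(lengths(per_allele) == 0L)) {
    stop_kdr("LCR assay failure: neither probe ligates on any allele",
             "kdr_assay_failure")
  }
  sizes <- c(wt = probes$wt_product_len, mut = probes$mut_product_len)
  bands <- sort(unique(unname(sizes[unlist(per_allele)])))
  call <- NULL
  if (!is.null(locus)) {
    aa_of <- c(wt = locus$wt_aa, mut = locus$mut_aa)
    allele_aas <- vapply(per_allele, function(lig) {
      if (length(lig) != 1L) NA_character_ else unname(aa_of[lig])
    }, character(1))
    if (anyNA(allele_aas)) {
      stop_kdr("ambiguous LCR ligation pattern for a single allele",
               "kdr_assay_failure")
    }
    call <- diploid_call(locus, pair_from_aas(allele_aas, locus, "LCR"))
  }
  structure(
    list(assay = "LCR", bands = bands, products_per_allele = per_allele, call = call),
    class = "assay_result"
  )
}

#' Call a codon variant directly from an anchored consensus sequence
#'
#' Anchors the locus codon by exact match of a reference flank (>= 20 bp
#' immediately upstream of the codon; the downstream flank is used as a
#' fallback), extracts the codon, expands ambiguity codes and translates.
#' One amino acid gives a homozygous call, two a heterozygote.
#'
#' @param sample_sequence IUPAC consensus sequence covering the locus codon.
#' @param locus a `resistance_locus`.
#' @param reference the reference transcript sequence the flanks are read from.
#' @param flank flank length in bp (>= 20).
#' @return a `diploid_call`.
#' @export
call_codon_variant <- function(sample_sequence, locus, reference, flank = 20L) {
  stopifnot(inherits(locus, "resistance_locus"), flank >= 20L)
  cs <- locus$codon_start
  up <- substr(reference, cs - flank, cs - 1L)
  dn <- substr(reference, cs + 3L, cs + 2L + flank)
  codon <- NA_character_
  hit <- iupac_match_positions(up, sample_sequence)
  # anchor flanks are concrete reference sequence; require a unique exact match
  if (nrow(hit) == 1L && grepl("^[ACGT]+$", up)) {
    codon <- substr(sample_sequence, hit[1L, "end"] + 1L, hit[1L, "end"] + 3L)
  } else {
    hit <- iupac_match_positions(dn, sample_sequence)
    if (nrow(hit) == 1L && grepl("^[ACGT]+$", dn)) {
      codon <- substr(sample_sequence, hit[1L, "start"] - 3L, hit[1L, "start"] - 1L)
    }
  }
  if (is.na(codon) || nchar(codon) != 3L) {
    stop_kdr(
      sprintf("codon at locus %s not covered / not anchorable in sample", locus$name),
      "kdr_coverage_error"
    )
  }
  aas <- translate_codon(codon)
  if (length(aas) > 2L || "*" %in% aas) {
    stop_kdr(
      sprintf("codon '%s' at locus %s expands to %d amino acids", codon, locus$name,
              length(aas)),
      "kdr_ambiguity_error"
    )
  }
  if (length(aas) == 1L) aas <- rep(aas, 2L)
  diploid_call(locus, aas)
}

#' Genotype one sample by all available assay routes and cross-check
#'
#' Runs the RFLP digest (locus 1014), the LCR assay (locus 918), and direct
#' codon calling at both loci, then verifies that every route that produced a
#' call agrees. Discordance (e.g. a corrupted restriction site) is an error
#' listing the conflicting calls.
#'
#' @param sample_sequence IUPAC consensus sequence (full transcript or any
#'   region covering the assays).
#' @param reference synthetic or real reference bundle as returned by
#'   [make_reference()]: list with `sequence`, `loci`, `kdr_amplicon`,
#'   `skdr_amplicon`, `enzyme`, `probes`.
#' @param max_het_sites passed to [expand_alleles()].
#' @return a `two_locus_genotype`; attribute `"provenance"` is a data.frame of
#'   (locus, method, call, bands).
#' @export
genotype_sample <- function(sample_sequence, reference, max_het_sites = 2L) {
  loci <- reference$loci
  prov <- list()
  add <- function(locus, method, call, bands) {
    prov[[length(prov) + 1L]] <<- data.frame(
      locus = locus, method = method, call = format(call),
      bands = paste(bands, collapse = ","), stringsAsFactors = FALSE
    )
  }

  rflp <- find_amplicon(sample_sequence, reference$kdr_amplicon)
  rflp_res <- digest(expand_alleles(rflp$sequence, max_het_sites),
                     reference$enzyme, loci[["1014"]])
  add("1014", "RFLP", rflp_res$call, rflp_res$bands)

  lcr_amp <- find_amplicon(sample_sequence, reference$skdr_amplicon)
  lcr_res <- lcr_genotype(expand_alleles(lcr_amp$sequence, max_het_sites),
                          reference$probes, loci[["918"]])
  add("918", "LCR", lcr_res$call, lcr_res$bands)

  cc_1014 <- call_codon_variant(sample_sequence, loci[["1014"]], reference$sequence)
  add("1014", "codon", cc_1014, integer(0))
  cc_918 <- call_codon_variant(sample_sequence, loci[["918"]], reference$sequence)
  add("918", "codon", cc_918, integer(0))

  prov <- do.call(rbind, prov)
  for (loc in c("1014", "918")) {
    calls <- unique(prov$call[prov$locus == loc])
    if (length(calls) > 1L) {
      stop_kdr(
        sprintf("discordant calls at locus %s: %s",
                loc,
                paste(sprintf("%s=%s", prov$method[prov$locus == loc],
                              prov$call[prov$locus == loc]), collapse = ", ")),
        "kdr_discordance"
      )
    }
  }
  g <- classify_genotype(rflp_res$call, lcr_res$call)
  attr(g, "provenance") <- prov
  g
}
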