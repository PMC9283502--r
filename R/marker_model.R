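# Domain model: resistance loci, codon translation with IUPAC ambiguity,
# diploid calls and two-locus kdr/super-kdr genotype classes.

#' IUPAC nucleotide ambiguity map
#'
#' Named character vector mapping each of the 15 IUPAC nucleotide codes to the
#' concrete bases it stands for (e.g. `Y` -> `"CT"`).
#' @export
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' The nine two-locus genotype strings in canonical (Table-header) order
#' @export
GENOTYPE_CLASSES_9 <- c(
  "L/L:M/M", "L/L:M/I", "L/L:I/I",
  "L/F:M/M", "L/F:M/I", "L/F:I/I",
  "F/F:M/M", "F/F:M/I", "F/F:I/I"
)

stop_kdr <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "kdrmonitor_error")))
}

#' Expand an IUPAC sequence into all concrete sequences
#'
#' @param x a single nucleotide string possibly containing IUPAC ambiguity codes.
#' @param max_sites maximum number of ambiguous positions allowed (`Inf` for no
#'   limit). More ambiguous sites than this signals an unusable consensus trace.
#' @return character vector of concrete `A/C/G/T` sequences (length
#'   `prod(expansions)`), in lexicographic expansion order.
#' @export
expand_iupac <- function(x, max_sites = Inf) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad)) {
    stop_kdr(
      sprintf("invalid (non-IUPAC) character '%s' at position %d", chars[bad[1]], bad[1]),
      "kdr_invalid_sequence"
    )
  }
  amb <- which(nchar(IUPAC_CODES[chars]) > 1L)
  if (length(amb) > max_sites) {
    stop_kdr(
      sprintf("%d ambiguous sites exceed the maximum of %s", length(amb), format(max_sites)),
      "kdr_ambiguity_overflow"
    )
  }
  if (!length(amb)) return(paste(chars, collapse = ""))
  pools <- lapply(chars, function(ch) strsplit(IUPAC_CODES[[ch]], "")[[1]])
  grid <- expand.grid(pools, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  apply(as.matrix(grid), 1L, paste, collapse = "")
}

#' Translate a codon, expanding IUPAC ambiguity codes
#'
#' Expands every ambiguity code in a 3-mer and translates each concrete codon
#' with the standard genetic code, returning the set of amino acids observed.
#' A heterozygous Sanger consensus codon such as `"YTT"` (Y = C/T) translates
#' to both leucine and phenylalanine.
#'
#' @param codon a 3-character nucleotide string over the IUPAC alphabet.
#' @return sorted character vector of unique single-letter amino acids
#'   (`"*"` for stop).
#' @examples
#' translate_codon("CTT") # "L"
#' translate_codon("YTT") # c("F", "L")
#' @export
translate_codon <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  if (nchar(codon) != 3L) {
    stop_kdr("codon must have length 3", "kdr_invalid_sequence")
  }
  concrete <- expand_iupac(codon)
  sort(unique(unname(Biostrings::GENETIC_CODE[concrete])))
}

#' Define a resistance locus under surveillance
#'
#' @param name short label, e.g. `"L1014F"`.
#' @param aa_position amino-acid position in Musca-orthologous numbering.
#' @param transcript_position 1-based coordinate of the variant nucleotide on
#'   the reference transcript.
#' @param codon_offset position (1-3) of the variant base within its codon.
#' @param wt_codon,mut_codon wild-type and mutant 3-mers; must differ at exactly
#'   the variant base.
#' @return an object of class `resistance_locus`.
#' @export
resistance_locus <- function(name, aa_position, transcript_position, codon_offset,
                             wt_codon, mut_codon) {
  stopifnot(codon_offset %in% 1:3, nchar(wt_codon) == 3L, nchar(mut_codon) == 3L)
  wt <- strsplit(toupper(wt_codon), "")[[1]]
  mt <- strsplit(toupper(mut_codon), "")[[1]]
  diff <- which(wt != mt)
  if (!identical(diff, as.integer(codon_offset))) {
    stop_kdr(
      sprintf("wt and mut codons must differ exactly at codon_offset %d", codon_offset),
      "kdr_invalid_locus"
    )
  }
  wt_aa <- translate_codon(wt_codon)
  mut_aa <- translate_codon(mut_codon)
  stopifnot(length(wt_aa) == 1L, length(mut_aa) == 1L)
  structure(
    list(
      name = name, aa_position = as.integer(aa_position),
      transcript_position = as.integer(transcript_position),
      codon_offset = as.integer(codon_offset),
      wt_codon = paste(wt, collapse = ""), mut_codon = paste(mt, collapse = ""),
      wt_aa = wt_aa, mut_aa = mut_aa,
      wt_base = wt[codon_offset], mut_base = mt[codon_offset],
      codon_start = as.integer(transcript_position - codon_offset + 1L)
    ),
    class = "resistance_locus"
  )
}

#' @export
print.resistance_locus <- function(x, ...) {
  cat(sprintf(
    "<resistance_locus> %s: aa %d (%s>%s), transcript pos %d (codon base %d, %s>%s)\n",
    x$name, x$aa_position, x$wt_aa, x$mut_aa, x$transcript_position,
    x$codon_offset, x$wt_base, x$mut_base
  ))
  invisible(x)
}

#' The two A. glycines vgsc surveillance loci (Musca numbering)
#'
#' `L1014F`: CTT -> TTT, variant C>T at transcript position 3070 (first codon
#' base). `M918I`: ATG -> ATA, variant G>A at 2784 (third codon base).
#' @return named list of two `resistance_locus` objects (`"1014"`, `"918"`).
#' @export
kdr_loci <- function() {
  list(
    `1014` = resistance_locus("L1014F", 1014, 3070, 1, "CTT", "TTT"),
    `918`  = resistance_locus("M918I", 918, 2784, 3, "ATG", "ATA")
  )
}

#' Diploid amino-acid call at one locus
#'
#' Alleles are an unordered pair; rendering is canonical wild-type-first
#' (`"L/F"`, never `"F/L"`).
#'
#' @param locus a `resistance_locus`.
#' @param alleles character vector of 2 single-letter amino acids, each equal to
#'   the locus wt or mut amino acid.
#' @return object of class `diploid_call`.
#' @export
diploid_call <- function(locus, alleles) {
  stopifnot(inherits(locus, "resistance_locus"), length(alleles) == 2L)
  ok <- alleles %in% c(locus$wt_aa, locus$mut_aa)
  if (!all(ok)) {
    stop_kdr(
      sprintf("allele(s) %s not valid for locus %s (expected %s or %s)",
              paste(alleles[!ok], collapse = ","), locus$name, locus$wt_aa, locus$mut_aa),
      "kdr_invalid_allele"
    )
  }
  # canonical order: wild type first
  alleles <- alleles[order(alleles != locus$wt_aa)]
  structure(list(locus = locus, alleles = alleles), class = "diploid_call")
}

#' @export
format.diploid_call <- function(x, ...) paste(x$alleles, collapse = "/")

#' @export
print.diploid_call <- function(x, ...) {
  cat(sprintf("<diploid_call> %s at %s (%s)\n", format(x), x$locus$name, zygosity(x)))
  invisible(x)
}

#' Zygosity of a diploid call
#' @param call a `diploid_call`.
#' @return one of `"hom-wt"`, `"het"`, `"hom-mut"`.
#' @export
zygosity <- function(call) {
  n_mut <- sum(call$alleles == call$locus$mut_aa)
  c("hom-wt", "het", "hom-mut")[n_mut + 1L]
}

#' Classify a two-locus genotype into kdr/super-kdr resistance classes
#'
#' Any 1014F allele with no 918I allele is kdr (het or hom by 1014 zygosity);
#' 1014F together with any 918I is super-kdr (homozygote only when both loci
#' are hom-mut); 918I without 1014F is labelled `"918-only"` (a class the field
#' tables report but do not name); L/L:M/M is wild type.
#'
#' @param call_1014,call_918 `diploid_call`s at aa positions 1014 and 918.
#' @return object of class `two_locus_genotype` with fields `call_1014`,
#'   `call_918`, `class_label`, `string` (nine-class `"L/F:M/I"` form).
#' @export
classify_genotype <- function(call_1014, call_918) {
  stopifnot(inherits(call_1014, "diploid_call"), inherits(call_918, "diploid_call"))
  if (call_1014$locus$aa_position != 1014L || call_918$locus$aa_position != 918L) {
    stop_kdr(
      sprintf("locus mismatch: got aa positions %d and %d, expected 1014 and 918",
              call_1014$locus$aa_position, call_918$locus$aa_position),
      "kdr_locus_mismatch"
    )
  }
  has_f <- any(call_1014$alleles == call_1014$locus$mut_aa)
  has_i <- any(call_918$alleles == call_918$locus$mut_aa)
  z1014 <- zygosity(call_1014)
  z918 <- zygosity(call_918)
  label <-
    if (!has_f && !has_i) "wild type"
    else if (has_f && !has_i) {
      if (z1014 == "hom-mut") "kdr homozygote" else "kdr heterozygote"
    } else if (has_f && has_i) {
      if (z1014 == "hom-mut" && z918 == "hom-mut") "super-kdr homozygote"
      else "super-kdr heterozygote"
    } else "918-only"
  structure(
    list(
      call_1014 = call_1014, call_918 = call_918, class_label = label,
      string = paste(format(call_1014), format(call_918), sep = ":")
    ),
    class = "two_locus_genotype"
  )
}

#' @export
format.two_locus_genotype <- function(x, ...) x$string

#' @export
print.two_locus_genotype <- function(x, ...) {
  cat(sprintf("<two_locus_genotype> %s (%s)\n", x$string, x$class_label))
  invisible(x)
}

#' Parse a nine-class genotype string
#'
#' Accepts `"X/Y:W/Z"` with X,Y in {L,F} and W,Z in {M,I} in either allele
#' order; renders canonically so `parse` then `format` round-trips onto the
#' canonical form (`"F/L:M/M"` -> `"L/F:M/M"`).
#'
#' @param text genotype string like `"L/F:M/I"`.
#' @param loci list as returned by [kdr_loci()].
#' @return a `two_locus_genotype`.
#' @export
parse_genotype_string <- function(text, loci = kdr_loci()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("^[LF]/[LF]:[MI]/[MI]$", text)) {
    stop_kdr(sprintf("malformed genotype string '%s'", text), "kdr_parse_error")
  }
  parts <- strsplit(strsplit(text, ":", fixed = TRUE)[[1]], "/", fixed = TRUE)
  classify_genotype(
    diploid_call(loci[["1014"]], parts[[1]]),
    diploid_call(loci[["918"]], parts[[2]])
  )
}

#' Load resistance-locus definitions from a DCF config file
#'
#' One record per locus (blank-line separated), Debian-control style fields:
#' `name`, `aa_position`, `transcript_position`, `codon_offset`, `wt_codon`,
#' `mut_codon`.
#'
#' @param path file path.
#' @return named list of `resistance_locus` (names = aa positions).
#' @export
read_locus_config <- function(path) {
  recs <- read.dcf(path)
  need <- c("name", "aa_position", "transcript_position", "codon_offset",
            "wt_codon", "mut_codon")
  missing_f <- setdiff(need, colnames(recs))
  if (length(missing_f)) {
    stop_kdr(paste("locus config missing field(s):", paste(missing_f, collapse = ", ")),
             "kdr_config_error")
  }
  loci <- lapply(seq_len(nrow(recs)), function(i) {
    resistance_locus(
      name = recs[i, "name"],
      aa_position = as.integer(recs[i, "aa_position"]),
      transcript_position = as.integer(recs[i, "transcript_position"]),
      codon_offset = as.integer(recs[i, "codon_offset"]),
      wt_codon = recs[i, "wt_codon"], mut_codon = recs[i, "mut_codon"]
    )
  })
  names(loci) <- vapply(loci, function(l) as.character(l$aa_position), character(1))
  loci
}

#' Write resistance-locus definitions to a DCF config file
#' @param loci named list of `resistance_locus`.
#' @param path file path.
#' @export
write_locus_config <- function(loci, path) {
  m <- do.call(rbind, lapply(loci, function(l) {
    cbind(name = l$name, aa_position = l$aa_position,
          transcript_position = l$transcript_position, codon_offset = l$codon_offset,
          wt_codon = l$wt_codon, mut_codon = l$mut_codon)
  }))
  write.dcf(m, path)
  invisible(path)
}
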