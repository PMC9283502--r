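# Shared fixtures built in code: the deterministic synthetic reference and a
# designed 16-individual cohort covering all nine two-locus genotype classes.

ref_fixture <- make_reference(seed = 1L)

designed_cohort <- local({
  haps <- expand.grid(h1 = HAPLOTYPES, h2 = HAPLOTYPES, stringsAsFactors = FALSE)
  loci <- kdr_loci()
  geno <- vapply(seq_len(nrow(haps)), function(i) {
    classify_genotype(
      diploid_call(loci[["1014"]], substr(c(haps$h1[i], haps$h2[i]), 1L, 1L)),
      diploid_call(loci[["918"]], substr(c(haps$h1[i], haps$h2[i]), 2L, 2L))
    )$string
  }, character(1))
  data.frame(
    sample_id = sprintf("d%02d", seq_len(nrow(haps))),
    hap1 = haps$h1, hap2 = haps$h2, genotype = geno,
    stringsAsFactors = FALSE
  )
})

# independent amino-acid lookup for the translation oracle (plain table,
# written down separately from the implementation's Biostrings lookup)
aa_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

iupac_table <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# brute-force oracle: expand IUPAC 3-mer by nested loops and translate
oracle_translate <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (a in strsplit(iupac_table[[ch[1]]], "")[[1]])
    for (b in strsplit(iupac_table[[ch[2]]], "")[[1]])
      for (d in strsplit(iupac_table[[ch[3]]], "")[[1]])
        out <- c(out, aa_table[[paste0(a, b, d)]])
  sort(unique(out))
}

# brute-force two-sided exact p for a 2xk table: enumerate every first row
oracle_fisher <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  lp_obs <- sum(lchoose(cs, tab[1, ])) - lchoose(sum(cs), r1)
  rows <- expand.grid(lapply(cs, function(c) 0:c))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  lp <- apply(rows, 1, function(a) sum(lchoose(cs, a))) - lchoose(sum(cs), r1)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}
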