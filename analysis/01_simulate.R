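#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth --
# reference transcript, assay definitions, a field cohort with consensus
# sequences, a selection experiment, and bioassay tables.

library(kdrmonitor)

seed <- 1L
dir.create("results", showWarnings = FALSE)

ref <- make_reference(seed)
write_fasta(c(vgsc_h1_synthetic = ref$sequence), "results/reference_synthetic.fasta",
            header = sprintf("synthetic vgsc-h1 transcript, seed=%d", seed))
write_locus_config(ref$loci, "results/loci.dcf")
cat(sprintf("reference: %d bp; kdr amplicon %d bp (%d-%d); BstEII wild-type digest %s\n",
            nchar(ref$sequence), ref$kdr_amplicon$expected_length,
            ref$kdr_amplicon$reference_interval[1], ref$kdr_amplicon$reference_interval[2],
            paste(digest(find_amplicon(ref$sequence, ref$kdr_amplicon)$sequence,
                         ref$enzyme)$bands, collapse = "+")))

pop <- sample_population(DEFAULT_HAPLOTYPE_FREQS, n = 400, seed = seed)
write.table(pop, "results/cohort_truth.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("cohort of", nrow(pop), "individuals; class spectrum:\n")
print(table(pop$class))

seqs <- render_sequences(pop, ref, noise_rate = 0, seed = seed)
write_fasta(seqs, "results/cohort_consensus.fasta",
            header = sprintf("per-individual IUPAC consensus, seed=%d", seed))

sel <- apply_selection(pop, DEFAULT_SELECTION, seed = seed)
write.table(rbind(cbind(group = "survivor", sel$survivors),
                  cbind(group = "moribund", sel$moribund)),
            "results/selection_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("selection: %d survivors / %d moribund\n",
            nrow(sel$survivors), nrow(sel$moribund)))

# two bioassay populations mirroring the susceptible / most-resistant pair;
# each gets a dilution series spanning its own response region, as assays are
# run in practice (both series inside the 0.0008-60 ug/ml assay range)
bio <- rbind(
  simulate_bioassay(b = 2.5, d = 1, e = 0.38, population = "susceptible",
                    doses = exp(seq(log(0.01), log(6), length.out = 8)), seed = seed),
  simulate_bioassay(b = 2.1, d = 1, e = 18.33, population = "resistant",
                    doses = exp(seq(log(0.5), log(60), length.out = 8)), seed = seed + 1L)
)
write.table(bio, "results/bioassay.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("bioassay tables written for", length(unique(bio$population)), "populations\n")
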