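#!/usr/bin/env Rscript
# Step 2 — map reads to the pangenome, QC coverage, call variants.
#
# Reads are mapped ungapped (21-mer seeds, <=5% mismatches, paralog-ambiguous
# reads discarded); per-site nucleotide counts feed the variant filters:
# depth >= 10 in every retained sample, exactly two alleles with pooled
# count >= 4, third-allele noise <= 2, pooled minor-allele frequency >= 2%.

library(symbiopop)

study <- "results/study"
seqs <- read_fasta(file.path(study, "pangenome.fasta"))
pg <- pangenome(names(seqs), unname(seqs),
                category = ifelse(grepl("^acc_", names(seqs)),
                                  "accessory", "core"),
                deme = ifelse(grepl("^acc_", names(seqs)),
                              as.integer(sub("^acc_d(\\d+).*", "\\1",
                                             names(seqs))), NA_integer_))
md <- read.delim(file.path(study, "metadata.tsv"))

aln <- lapply(md$sample_id, function(s)
  map_reads(file.path(study, "reads", paste0(s, ".fastq")), pg,
            sample_id = s))
names(aln) <- md$sample_id
for (s in md$sample_id) {
  st <- attr(aln[[s]], "stats")
  cat(sprintf("%-15s mapped %5d  unmapped %5d (host + errors)  ambiguous %d\n",
              s, st$n_mapped, st$n_unmapped, st$n_ambiguous))
  write_sam(aln[[s]], pg, file.path(study, paste0(s, ".sam")))
}

pc <- pileup_counts(aln, pg)
cat("\nCoverage:\n"); print(pc$coverage)
qc <- sample_qc(pc$coverage, min_mean_depth = 10)
cat("Retained:", paste(qc$retained, collapse = ", "), "\n")
if (length(qc$low_coverage))
  cat("Low coverage (secondary analysis):",
      paste(qc$low_coverage, collapse = ", "), "\n")

v <- call_variants(pc$counts, qc$retained)
cat("\nFilter ledger:\n"); print(v$filter_ledger)

truth <- read.delim(file.path(study, "truth_sites.tsv"))
recall <- mean(paste(truth$gene_id, truth$pos) %in%
                 paste(v$sites$gene_id, v$sites$pos))
cat(sprintf("\n%d biallelic variant sites called; %.0f%% of planted sites recovered\n",
            nrow(v$sites), 100 * recall))

out <- cbind(v$sites,
             setNames(as.data.frame(v$ref_counts), paste0(v$samples, "_ref")),
             setNames(as.data.frame(v$alt_counts), paste0(v$samples, "_alt")))
write.table(out, file.path(study, "variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(counts = pc$counts, variants = v),
        file.path(study, "counts.rds"))  # scratch for steps 3-4
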