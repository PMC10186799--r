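#!/usr/bin/env Rscript
# Step 3 — population structure: Hudson F_ST and Bray-Curtis ordination.
#
# Each sample is treated as a population (read depth = allele draws); F_ST
# is also computed between samples pooled by vent field and by lifestyle.
# The expectation under the simulated design: strong differentiation by
# field, near-zero by lifestyle, and PCoA axis 1 splitting the fields.

library(symbiopop)

study <- "results/study"
md <- read.delim(file.path(study, "metadata.tsv"))
st <- readRDS(file.path(study, "counts.rds"))
v <- st$variants

for (g in c("sample", "vent_field", "lifestyle")) {
  fr <- pairwise_fst(v, md, g)
  cat("\nPairwise F_ST, grouping =", g, "\n")
  print(round(fr$fst, 3))
  fr$pairs$band <- classify_differentiation(fr$pairs$fst)
  write.table(fr$pairs, file.path(study, paste0("fst_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

field_fst <- pairwise_fst(v, md, "vent_field")$fst[1, 2]
life_fst <- pairwise_fst(v, md, "lifestyle")$fst[1, 2]
cat(sprintf("\nPooled F_ST by vent field: %.3f (%s); by lifestyle: %.3f (%s)\n",
            field_fst, classify_differentiation(field_fst),
            life_fst, classify_differentiation(life_fst)))

# Bray-Curtis on per-site nucleotide proportions at the variant sites
key <- paste(st$counts$sites$gene_id, st$counts$sites$pos)
idx <- match(paste(v$sites$gene_id, v$sites$pos), key)
nc_v <- structure(list(sites = st$counts$sites[idx, ], samples = v$samples,
                       counts = st$counts$counts[idx, v$samples, ,
                                                 drop = FALSE]),
                  class = "nuc_counts")
bc <- bray_curtis_matrix(nc_v)
p <- pcoa(bc)
cat(sprintf("\nPCoA: axis 1 explains %.1f%%, axis 2 %.1f%%\n",
            100 * p$proportion_explained[1], 100 * p$proportion_explained[2]))
coords <- data.frame(sample_id = rownames(p$coordinates), p$coordinates)
write.table(merge(coords, md), file.path(study, "pcoa_bray_curtis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  gg <- plot_pcoa(p, md)
  ggplot2::ggsave(file.path(study, "pcoa_bray_curtis.pdf"), gg,
                  width = 5, height = 4)
}
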