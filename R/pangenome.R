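#' Construct a pangenome reference object
#'
#' The pangenome is the mapping frame of reference: one sequence per gene
#' cluster, flagged core or accessory. It stands in for the gene-cluster
#' reference a pangenome builder would produce from per-sample genome
#' assemblies.
#'
#' @param gene_ids Unique gene cluster identifiers.
#' @param sequences Nucleotide sequences over `{A,C,G,T}`, parallel to
#'   `gene_ids`.
#' @param category `"core"` or `"accessory"` per gene.
#' @param deme Integer deme owning each accessory gene (`NA` for core).
#' @param category_label Optional functional-category label per gene.
#' @return A `pangenome` object: `$genes` (data.frame of gene_id, length,
#'   category, deme, category_label) and `$seq` (named character vector).
#' @export
pangenome <- function(gene_ids, sequences, category,
                      deme = rep(NA_integer_, length(gene_ids)),
                      category_label = rep(NA_character_, length(gene_ids))) {
  if (anyDuplicated(gene_ids)) stop_sym("gene_ids must be unique")
  if (any(nchar(sequences) == 0L)) stop_sym("sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequences))) stop_sym("sequences must be over {A,C,G,T}")
  if (!any(category == "core")) stop_sym("pangenome needs at least 1 core gene")
  genes <- data.frame(gene_id = gene_ids, length = nchar(sequences),
                      category = category, deme = as.integer(deme),
                      category_label = category_label,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, seq = setNames(sequences, gene_ids)),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat("pangenome:", nrow(x$genes), "gene clusters (",
      sum(x$genes$category == "core"), "core,",
      sum(x$genes$category == "accessory"), "accessory ),",
      sum(x$genes$length), "bp total\n")
  invisible(x)
}

#' Generate a synthetic pangenome
#'
#' Draws random gene cluster sequences: `n_core_genes` core genes shared by
#' all strains plus `n_accessory_per_deme` accessory genes private to each
#' deme (tagged with the owning deme). Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return A [pangenome()] object.
#' @export
generate_pangenome <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "pangenome"), {
    n_acc <- config$n_demes * config$n_accessory_per_deme
    n <- config$n_core_genes + n_acc
    span <- config$gene_length_range[2] - config$gene_length_range[1] + 1L
    lens <- config$gene_length_range[1] + sample.int(span, n, replace = TRUE) - 1L
    seqs <- random_dna(lens)
    ids <- c(sprintf("core_%04d", seq_len(config$n_core_genes)),
             if (n_acc > 0)
               sprintf("acc_d%d_%03d",
                       rep(seq_len(config$n_demes), each = config$n_accessory_per_deme),
                       rep(seq_len(config$n_accessory_per_deme), config$n_demes)))
    cat_ <- c(rep("core", config$n_core_genes), rep("accessory", n_acc))
    deme <- c(rep(NA_integer_, config$n_core_genes),
              if (n_acc > 0) rep(seq_len(config$n_demes),
                                 each = config$n_accessory_per_deme))
    pangenome(ids, seqs, cat_, deme)
  })
}
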