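new_alignment_set <- function(dt, sample_id = NA_character_,
                              stats = list()) {
  data.table::setDT(dt)
  data.table::setattr(dt, "class",
                      c("alignment_set", "data.table", "data.frame"))
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "stats", stats)
  dt
}

#' @export
print.alignment_set <- function(x, ...) {
  st <- attr(x, "stats")
  cat("alignment_set (", attr(x, "sample_id"), "): ", nrow(x),
      " alignments", sep = "")
  if (length(st))
    cat(" | unmapped ", st$n_unmapped, ", ambiguous ", st$n_ambiguous,
        ", skipped ", st$n_skipped, sep = "")
  cat("\n")
  invisible(x)
}

#' Map reads to a pangenome (ungapped seed-and-extend)
#'
#' Exact seeds of length `k_map` taken at offsets 0, k, 2k, ... along the read
#' (both orientations) are looked up in an index of pangenome k-mers; every
#' candidate placement is scored by full-read Hamming distance. The best
#' (fewest-mismatch) placement wins; reads whose best placement exceeds
#' `max_mismatch_frac`, or with co-best placements on different genes
#' (paralogs), are discarded as unmapped/ambiguous. Reads with non-ACGT
#' symbols are skipped with a warning tally. Alignments are reported on the
#' gene's forward strand (the aligned sequence of a reverse-strand read is
#' its reverse complement).
#'
#' @param reads Named character vector of read sequences, or a FASTQ path.
#' @param pg A [pangenome()].
#' @param max_mismatch_frac Maximum mismatches as a fraction of read length.
#' @param k_map Seed length (<= 31).
#' @param sample_id Optional sample label carried on the result.
#' @return An `alignment_set`: data.table of read_id, gene_id, start
#'   (0-based), strand, seq (gene-forward aligned sequence), n_mismatch; with
#'   mapping statistics in `attr(, "stats")`.
#' @export
map_reads <- function(reads, pg, max_mismatch_frac = 0.05, k_map = 21,
                      sample_id = NA_character_) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads))
    reads <- read_fastq(reads)
  if (!inherits(pg, "pangenome") || nrow(pg$genes) == 0L)
    stop_sym("empty or invalid pangenome")
  if (k_map < 1 || k_map > 31) stop_sym("k_map must be in 1..31")
  if (length(reads) && max(nchar(reads)) > min(pg$genes$length))
    stop_sym("reads longer than the shortest gene are not supported")

  res <- cpp_map_reads(unname(reads), unname(pg$seq), as.integer(k_map),
                       max_mismatch_frac)
  n_skip <- sum(res$status == 3L)
  if (n_skip > 0)
    warning(n_skip, " read(s) with non-ACGT symbols skipped", call. = FALSE)
  rc <- res$rc == 1L
  aligned <- unname(reads)[res$read_idx]
  if (any(rc)) aligned[rc] <- revcomp(aligned[rc])
  dt <- data.table::data.table(
    read_id = names(reads)[res$read_idx] %||% as.character(res$read_idx),
    gene_id = pg$genes$gene_id[res$gene_idx],
    start = res$start,
    strand = ifelse(rc, "-", "+"),
    seq = aligned,
    n_mismatch = res$n_mismatch)
  new_alignment_set(dt, sample_id, list(
    n_total = length(reads), n_mapped = nrow(dt),
    n_unmapped = sum(res$status == 1L),
    n_ambiguous = sum(res$status == 2L), n_skipped = n_skip))
}

#' Write an alignment set as SAM
#'
#' Minimal SAM 1.6 output: `@SQ` line per pangenome gene, one record per
#' alignment (ungapped, full-length match CIGAR), internal 0-based starts
#' converted to SAM 1-based `POS`, reverse-strand alignments flagged 16 with
#' the sequence stored gene-forward as SAM requires.
#'
#' @param aln An `alignment_set`.
#' @param pg The [pangenome()] the alignments refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, pg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", pg$genes$gene_id, pg$genes$length),
             con)
  if (nrow(aln)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       aln$read_id, ifelse(aln$strand == "-", 16L, 0L),
                       aln$gene_id, aln$start + 1L, nchar(aln$seq), aln$seq,
                       aln$n_mismatch), con)
  }
  invisible(path)
}

#' Read alignments from SAM
#'
#' Accepts externally produced alignments (including paired-end runs) as an
#' alternative to the internal mapper. Converts mapped, primary,
#' non-supplementary records via Rsamtools; SAM 1-based positions become
#' internal 0-based starts. Reference names must all exist in the pangenome.
#' Mismatch counts are recomputed against the pangenome (ungapped;
#' soft-clips and indels are not supported).
#'
#' @param path SAM file path.
#' @param pg The [pangenome()] the alignments refer to.
#' @param sample_id Optional sample label.
#' @return An `alignment_set`.
#' @export
read_sam <- function(path, pg, sample_id = NA_character_) {
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  bad <- setdiff(names(hdr), pg$genes$gene_id)
  if (length(bad))
    stop_sym("SAM reference name(s) not in pangenome: ",
             paste(bad, collapse = ", "))
  x <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "seq")))[[1]]
  flag <- x$flag
  keep <- which(bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
                  bitwAnd(flag, 0x800L) == 0L)
  gene_id <- as.character(x$rname[keep])
  start <- x$pos[keep] - 1L
  seqs <- as.character(x$seq[keep])
  glen <- pg$genes$length[match(gene_id, pg$genes$gene_id)]
  if (any(start < 0L | start + nchar(seqs) > glen))
    stop_sym("alignment extends beyond its reference gene")
  ref_piece <- substr(pg$seq[gene_id], start + 1L, start + nchar(seqs))
  nm <- as.integer(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                          seqs, ref_piece, USE.NAMES = FALSE))
  dt <- data.table::data.table(
    read_id = x$qname[keep], gene_id = gene_id, start = start,
    strand = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+"),
    seq = seqs, n_mismatch = nm)
  new_alignment_set(dt, sample_id,
                    list(n_total = length(flag), n_mapped = nrow(dt),
                         n_unmapped = sum(bitwAnd(flag, 0x4L) != 0L),
                         n_ambiguous = 0L, n_skipped = 0L))
}
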