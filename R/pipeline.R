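PIPELINE_STAGES <- c("simulate", "map", "variants", "structure",
                     "genecontent", "markers")

default_thresholds <- function() {
  list(k_map = 21, max_mismatch_frac = 0.05, min_mean_depth = 10,
       min_site_depth = 10, min_allele_count = 4, noise_allele_max = 2,
       min_maf = 0.02, secondary_min_site_depth = 3, theta_present = 0.25,
       theta_absent = 0.05, k_marker = 31, min_hit_frac = 0.5, margin = 2.0,
       fold_threshold = 10)
}

threshold_ranges <- list(
  k_map = c(1, 31), max_mismatch_frac = c(0, 1), min_mean_depth = c(0, Inf),
  min_site_depth = c(0, Inf), min_allele_count = c(0, Inf),
  noise_allele_max = c(0, Inf), min_maf = c(0, 0.5),
  secondary_min_site_depth = c(0, Inf), theta_present = c(0, Inf),
  theta_absent = c(0, Inf), k_marker = c(1, 31), min_hit_frac = c(0, 1),
  margin = c(1, Inf), fold_threshold = c(1, Inf))

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), injects defaults, rejects unknown
#' keys and out-of-range thresholds, and verifies that referenced paths
#' exist — reporting every problem at once. The resolved configuration is
#' echoed into the output directory when the pipeline runs.
#'
#' @param config Path to a YAML file, or a list with (all optional):
#'   `seed`, `out_dir`, `stages`, `groupings`, `simulation` (arguments to
#'   [sim_config()] plus `host_per_deme`, `free_per_deme`, `mean_depth`),
#'   `paths` (`pangenome`, `reads` as a sample->FASTQ map, `sam` as a
#'   sample->SAM map, `metadata` TSV), `thresholds`.
#' @return A validated `run_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_sym("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  known_top <- c("seed", "out_dir", "stages", "groupings", "simulation",
                 "paths", "thresholds")
  extra <- setdiff(names(config), known_top)
  if (length(extra))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(extra, collapse = ", ")))

  th <- default_thresholds()
  if (!is.null(config$thresholds)) {
    extra <- setdiff(names(config$thresholds), names(th))
    if (length(extra))
      problems <- c(problems, paste0("unknown threshold(s): ",
                                     paste(extra, collapse = ", ")))
    th <- modifyList(th, config$thresholds[setdiff(names(config$thresholds),
                                                   extra)])
  }
  for (nm in names(threshold_ranges)) {
    r <- threshold_ranges[[nm]]
    if (!is.numeric(th[[nm]]) || th[[nm]] < r[1] || th[[nm]] > r[2])
      problems <- c(problems, paste0("threshold ", nm, " out of range [",
                                     r[1], ", ", r[2], "]"))
  }
  if (is.numeric(th$theta_absent) && is.numeric(th$theta_present) &&
      th$theta_absent >= th$theta_present)
    problems <- c(problems, "theta_absent must be < theta_present")

  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad, collapse = ", ")))
  groupings <- config$groupings %||% c("vent_field", "lifestyle")
  bad <- setdiff(groupings, c("sample", "vent_field", "lifestyle", "deme"))
  if (length(bad))
    problems <- c(problems, paste0("unknown grouping(s): ",
                                   paste(bad, collapse = ", ")))

  paths <- config$paths %||% list()
  known_paths <- c("pangenome", "reads", "sam", "metadata", "variants")
  extra <- setdiff(names(paths), known_paths)
  if (length(extra))
    problems <- c(problems, paste0("unknown path key(s): ",
                                   paste(extra, collapse = ", ")))
  for (p in c(unlist(paths[intersect(names(paths), known_paths)]))) {
    if (!file.exists(p))
      problems <- c(problems, paste0("path does not exist: ", p))
  }
  if (!is.null(paths$metadata) && file.exists(paths$metadata)) {
    md <- read_tsv_prov(paths$metadata)
    if (anyDuplicated(md$sample_id))
      problems <- c(problems, "duplicate sample_id in metadata")
  }

  sim <- config$simulation %||% list()
  known_sim <- c(setdiff(names(formals(sim_config)), c("samples", "seed")),
                 "host_per_deme", "free_per_deme", "mean_depth")
  extra <- setdiff(names(sim), known_sim)
  if (length(extra))
    problems <- c(problems, paste0("unknown simulation key(s): ",
                                   paste(extra, collapse = ", ")))

  if (length(problems))
    stop_sym("invalid configuration:\n  - ",
             paste(problems, collapse = "\n  - "))

  structure(list(seed = as.integer(config$seed %||% 1L),
                 out_dir = config$out_dir %||% "symbiopop_run",
                 stages = stages, groupings = groupings,
                 simulation = sim, paths = paths, thresholds = th),
            class = "run_config")
}

build_sim_config <- function(rc) {
  sim <- rc$simulation
  layout <- list(n_demes = sim$n_demes %||% 2,
                 host_per_deme = sim$host_per_deme %||% 2,
                 free_per_deme = sim$free_per_deme %||% 1,
                 mean_depth = sim$mean_depth %||% 20)
  args <- sim[setdiff(names(sim),
                      c("host_per_deme", "free_per_deme", "mean_depth"))]
  args$samples <- do.call(default_samples, layout)
  args$n_demes <- layout$n_demes
  args$seed <- rc$seed
  do.call(sim_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> map -> variants -> structure -> genecontent ->
#' markers in order (restricted to `config$stages`; stages whose inputs are
#' supplied precomputed via `config$paths` skip the simulation). Samples
#' failing coverage QC are excluded from the primary variant run and folded
#' into a secondary run restricted to sites meeting a reduced depth floor in
#' all samples. All tabular outputs are TSV with '#' provenance headers; a
#' run report (stage provenance, QC partition, site-count ledger, output
#' manifest with checksums) is written as JSON.
#'
#' @param config A `run_config` from [validate_config()], a list, or a YAML
#'   path.
#' @return The run report, invisibly (list; also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  rc <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(rc), file.path(rc$out_dir, "config_resolved.yaml"))
  th <- rc$thresholds
  report <- list(seed = rc$seed, stages_run = character(),
                 parameters = th, provenance = list())
  outputs <- character()
  log_line <- function(stage, msg)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)

  run_stage <- function(stage, fn) {
    if (!stage %in% rc$stages) return(invisible(NULL))
    before <- list.files(rc$out_dir, recursive = TRUE, full.names = TRUE)
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      created <- setdiff(list.files(rc$out_dir, recursive = TRUE,
                                    full.names = TRUE), before)
      for (f in created) file.rename(f, paste0(f, ".partial"))
      stop_sym("stage '", stage, "' failed: ", conditionMessage(e))
    })
    report$stages_run <<- c(report$stages_run, stage)
    invisible(ok)
  }

  env <- new.env()

  run_stage("simulate", function() {
    log_line("simulate", "generating pangenome, strains and reads")
    scfg <- build_sim_config(rc)
    env$sim <- simulate_metagenomes(scfg)
    env$pg <- env$sim$pangenome
    env$metadata <- sample_metadata(env$sim)
    write_fasta(env$pg$seq, file.path(rc$out_dir, "pangenome.fasta"))
    write_sample_fastq(env$sim, file.path(rc$out_dir, "reads"))
    write_tsv_prov(env$metadata, file.path(rc$out_dir, "metadata.tsv"),
                   "sample metadata (simulated)")
    write_tsv_prov(env$sim$truth$sites,
                   file.path(rc$out_dir, "truth_sites.tsv"),
                   "planted variant sites (simulation ground truth)")
    report$provenance$simulate <<- list(
      n_samples = length(env$sim$reads),
      n_reads = sum(vapply(env$sim$reads, length, integer(1))),
      fst_target = scfg$fst_target, n_sites = scfg$n_variant_sites)
  })

  # precomputed inputs take precedence over simulation outputs
  if (!is.null(rc$paths$pangenome)) env$pg <- {
    s <- read_fasta(rc$paths$pangenome)
    pangenome(names(s), unname(s), rep("core", length(s)))
  }
  if (!is.null(rc$paths$metadata))
    env$metadata <- read_tsv_prov(rc$paths$metadata)
  if (!is.null(rc$paths$variants))
    env$variants <- read_variants_tsv(rc$paths$variants)

  run_stage("map", function() {
    if (is.null(env$pg)) stop_sym("no pangenome available")
    env$aln <- list()
    if (!is.null(rc$paths$sam)) {
      for (sid in names(rc$paths$sam))
        env$aln[[sid]] <- read_sam(rc$paths$sam[[sid]], env$pg, sid)
    } else {
      read_sets <- if (!is.null(rc$paths$reads))
        lapply(rc$paths$reads, read_fastq)
      else lapply(env$sim$reads, identity)
      for (sid in names(read_sets)) {
        env$aln[[sid]] <- map_reads(read_sets[[sid]], env$pg,
                                    th$max_mismatch_frac, th$k_map, sid)
        write_sam(env$aln[[sid]], env$pg,
                  file.path(rc$out_dir, paste0(sid, ".sam")))
      }
    }
    log_line("map", paste(length(env$aln), "samples mapped"))
    report$provenance$map <<- list(
      k_map = th$k_map, max_mismatch_frac = th$max_mismatch_frac,
      stats = lapply(env$aln, attr, "stats"))
  })

  run_stage("variants", function() {
    pc <- pileup_counts(env$aln, env$pg)
    env$nc <- pc$counts
    env$coverage <- pc$coverage
    write_tsv_prov(pc$coverage, file.path(rc$out_dir, "coverage.tsv"),
                   "per-sample mean depth and breadth over the pangenome")
    qc <- sample_qc(pc$coverage, th$min_mean_depth)
    env$qc <- qc
    env$variants <- call_variants(env$nc, qc$retained, th$min_site_depth,
                                  th$min_allele_count, th$noise_allele_max,
                                  th$min_maf)
    write_tsv_prov(cbind(env$variants$sites,
                         setNames(as.data.frame(env$variants$ref_counts),
                                  paste0(env$variants$samples, "_ref")),
                         setNames(as.data.frame(env$variants$alt_counts),
                                  paste0(env$variants$samples, "_alt"))),
                   file.path(rc$out_dir, "variants.tsv"),
                   "filtered biallelic variants with per-sample counts")
    if (length(qc$low_coverage)) {
      env$variants_secondary <- call_variants(
        env$nc, c(qc$retained, qc$low_coverage),
        th$secondary_min_site_depth, th$min_allele_count,
        th$noise_allele_max, th$min_maf)
      write_tsv_prov(env$variants_secondary$sites,
                     file.path(rc$out_dir, "variants_secondary.tsv"),
                     "secondary run including low-coverage samples")
    }
    log_line("variants", paste(nrow(env$variants$sites), "variant sites"))
    report$provenance$variants <<- list(
      retained = qc$retained, low_coverage = qc$low_coverage,
      filter_ledger = as.list(env$variants$filter_ledger))
  })

  run_stage("structure", function() {
    groupings <- unique(c("sample", rc$groupings))
    env$fst <- list()
    for (g in groupings) {
      fr <- pairwise_fst(env$variants, env$metadata, g)
      env$fst[[g]] <- fr
      write_tsv_prov(fr$pairs,
                     file.path(rc$out_dir, paste0("fst_", g, ".tsv")),
                     paste("pairwise Hudson F_ST, grouping:", g))
    }
    if (!is.null(env$nc)) {
      vc_sites <- pileup_sites_subset(env$nc, env$variants)
      bc <- bray_curtis_matrix(vc_sites)
      env$bc_pcoa <- pcoa(bc, n_axes = min(2, nrow(bc) - 1))
      coords <- data.frame(sample_id = rownames(env$bc_pcoa$coordinates),
                           env$bc_pcoa$coordinates)
      write_tsv_prov(coords, file.path(rc$out_dir, "pcoa_bray_curtis.tsv"),
                     sprintf("PCoA on Bray-Curtis; proportion explained: %s",
                             paste(sprintf("%.3f",
                                           env$bc_pcoa$proportion_explained),
                                   collapse = ", ")))
    }
    log_line("structure", "F_ST and Bray-Curtis PCoA written")
  })

  run_stage("genecontent", function() {
    depths <- gene_depths(env$aln[env$variants$samples], env$pg)
    env$presence <- call_presence(depths, th$theta_present, th$theta_absent)
    pm <- as.data.frame(unclass(env$presence))
    write_tsv_prov(cbind(gene_id = rownames(env$presence), pm),
                   file.path(rc$out_dir, "gene_presence.tsv"),
                   "gene presence (1) / absence (0) / uncertain (NA)")
    jd <- jaccard_matrix(env$presence)
    env$jaccard_pcoa <- pcoa(jd, n_axes = min(2, nrow(jd) - 1))
    env$unique_genes <- list()
    for (g in setdiff(rc$groupings, "sample")) {
      grp <- setNames(as.character(env$metadata[[g]]),
                      env$metadata$sample_id)
      ug <- unique_genes(env$presence, grp)
      env$unique_genes[[g]] <- ug
      write_tsv_prov(ug$genes,
                     file.path(rc$out_dir, paste0("unique_genes_", g, ".tsv")),
                     paste("group-unique genes, grouping:", g))
    }
    log_line("genecontent", "presence matrix and unique genes written")
  })

  run_stage("markers", function() {
    rows <- list()
    for (scen in c("gill", "fluid")) {
      ms <- generate_marker_read_sets(scen,
                                      seed = derive_seed(rc$seed,
                                                         paste0("marker_", scen)))
      db <- build_marker_index(ms$databases, th$k_marker)
      cl <- classify_reads(ms$reads, db, th$min_hit_frac, th$margin)
      rows[[scen]] <- marker_ratio(cl$counts, cl$n_total, sample_id = scen)
    }
    rep_df <- do.call(rbind, rows)
    rep_df$flagged <- flag_lifestyle(rep_df$ratio,
                                     is_host = rep_df$sample_id == "gill",
                                     fold_threshold = th$fold_threshold)
    env$marker_report <- rep_df
    write_tsv_prov(rep_df, file.path(rc$out_dir, "marker_report.tsv"),
                   "16S:CO1 marker-read ratio test (synthetic scenarios)")
    log_line("markers", "marker ratio report written")
  })

  files <- list.files(rc$out_dir, recursive = TRUE)
  report$outputs <- lapply(files, function(f) list(
    path = f, md5 = unname(tools::md5sum(file.path(rc$out_dir, f)))))
  jsonlite::write_json(report, file.path(rc$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(report, list(env = env)))
}

#' Read a variant table written by the pipeline
#'
#' Inverse of the `variants.tsv` output of [run_pipeline()] (site columns
#' plus `<sample>_ref` / `<sample>_alt` count columns), enabling
#' structure-only re-runs on a precomputed table.
#'
#' @param path Path to a variants TSV.
#' @return A `variant_table`.
#' @export
read_variants_tsv <- function(path) {
  x <- read_tsv_prov(path)
  ref_cols <- grep("_ref$", names(x), value = TRUE)
  samples <- sub("_ref$", "", ref_cols)
  structure(list(
    sites = x[c("gene_id", "pos", "ref", "alt", "maf")],
    ref_counts = as.matrix(setNames(x[paste0(samples, "_ref")], samples)),
    alt_counts = as.matrix(setNames(x[paste0(samples, "_alt")], samples)),
    samples = samples,
    filter_ledger = NULL), class = "variant_table")
}

# nucleotide counts restricted to the variant sites of v (and its samples)
pileup_sites_subset <- function(nc, v) {
  key_nc <- paste(nc$sites$gene_id, nc$sites$pos)
  key_v <- paste(v$sites$gene_id, v$sites$pos)
  idx <- match(key_v, key_nc)
  if (anyNA(idx)) stop_sym("variant sites missing from count matrix")
  structure(list(sites = nc$sites[idx, , drop = FALSE], samples = v$samples,
                 counts = nc$counts[idx, v$samples, , drop = FALSE]),
            class = "nuc_counts")
}
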