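# Orchestration: a single structured config drives design -> simulate ->
# normalize/QC -> enrich -> interact, writing every table as CSV plus a JSON
# run-metadata file, so a fixed (config, seed) reproduces the output bundle
# byte for byte. run_demo() simulates its own screen; run_analysis() starts
# from user-supplied counts and shares the entire downstream code path.

#' Build a run configuration
#'
#' @param pos1_genes,pos2_genes Gene lists for the two library slots.
#' @param guides_per_gene Guides per targeted gene (both slots).
#' @param ntc_per_position Non-targeting guides per slot.
#' @param design A [screen_design()].
#' @param truth A [fitness_truth()] (simulation only).
#' @param noise A [noise_model()].
#' @param pseudocount CPM pseudocount.
#' @param fdr Enrichment FDR threshold.
#' @param alpha Interaction significance level.
#' @param watch_genes Genes whose association fraction among enriched
#'   constructs is reported.
#' @param seed Integer seed recorded in the run metadata.
#' @return A `run_config` list.
#' @export
run_config <- function(pos1_genes, pos2_genes, guides_per_gene = 3,
                       ntc_per_position = 10, design = screen_design(),
                       truth = fitness_truth(), noise = noise_model(),
                       pseudocount = 1, fdr = 0.05, alpha = 0.001,
                       watch_genes = character(0), seed = 1L) {
  cfg <- structure(list(pos1_genes = pos1_genes, pos2_genes = pos2_genes,
                        guides_per_gene = guides_per_gene,
                        ntc_per_position = ntc_per_position,
                        design = design, truth = truth, noise = noise,
                        pseudocount = pseudocount, fdr = fdr, alpha = alpha,
                        watch_genes = watch_genes, seed = as.integer(seed)),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!length(cfg$pos1_genes) || !length(cfg$pos2_genes))
    fail("config error: gene lists must be non-empty")
  if (!inherits(cfg$design, "screen_design")) fail("config error: design is not a screen_design")
  if (!inherits(cfg$truth, "fitness_truth")) fail("config error: truth is not a fitness_truth")
  if (!inherits(cfg$noise, "noise_model")) fail("config error: noise is not a noise_model")
  if (cfg$fdr < 0 || cfg$fdr > 1 || cfg$alpha < 0 || cfg$alpha > 1)
    fail("config error: fdr and alpha must lie in [0, 1]")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; `design`, `truth$beta1/beta2`,
#' `truth$interactions` and scalar noise parameters are nested maps.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  des <- do.call(screen_design, y$design %||% list())
  tr <- fitness_truth(
    beta1 = unlist(y$truth$beta1) %||% numeric(0),
    beta2 = unlist(y$truth$beta2) %||% numeric(0),
    interactions = if (!is.null(y$truth$interactions))
      do.call(rbind, lapply(y$truth$interactions, as.data.frame)) else NULL
  )
  nz <- noise_model(plasmid_sigma = y$noise$plasmid_sigma %||% 0.5,
                    nb_dispersion = y$noise$nb_dispersion %||% 0.05)
  run_config(pos1_genes = y$pos1_genes, pos2_genes = y$pos2_genes,
             guides_per_gene = y$guides_per_gene %||% 3,
             ntc_per_position = y$ntc_per_position %||% 10,
             design = des, truth = tr, noise = nz,
             pseudocount = y$pseudocount %||% 1, fdr = y$fdr %||% 0.05,
             alpha = y$alpha %||% 0.001,
             watch_genes = unlist(y$watch_genes) %||% character(0),
             seed = y$seed %||% 1L)
}

#' Demonstration configuration
#'
#' A small planted screen: 12 slot-1 genes of which Jak1 and Jak2 carry a
#' strong resistance effect (beta = 3), 6 slot-2 tumor suppressors, one
#' additive and one subtractive planted interaction on otherwise neutral
#' genes, 2 guides/gene, 8 NTCs per slot, 2 E:T ratios x 2 replicates at
#' moderate depth. Runs in seconds.
#'
#' @param seed Integer seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L) {
  pos1 <- c("Jak1", "Jak2", "Ifngr1", "Stat1", "B2m", "Tap1",
            "Ptpn2", "Adar", "Atg7", "Fitm2", "Serpinb9", "Cd47")
  pos2 <- c("Trp53", "Pten", "Apc", "Kmt2d", "Rb1", "Nf1")
  run_config(
    pos1_genes = pos1, pos2_genes = pos2,
    guides_per_gene = 2, ntc_per_position = 8,
    design = screen_design(et_ratios = c(2, 5), replicates = 2, depth = 1e6,
                           coverage = 500),
    truth = fitness_truth(
      beta1 = c(Jak1 = 3, Jak2 = 3),
      interactions = data.frame(gene1 = c("Ptpn2", "Atg7"),
                                gene2 = c("Trp53", "Kmt2d"),
                                gamma = c(1.5, -1.5))
    ),
    alpha = 0.05, fdr = 0.1, watch_genes = c("Jak1", "Jak2"), seed = seed
  )
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# shared downstream analysis for run_demo()/run_analysis()
analyze_counts <- function(cm, lib, cfg, out_dir) {
  nm <- cpm_log_normalize(cm, pseudocount = cfg$pseudocount)
  post <- select_samples(nm, condition = "post_coculture")
  ref <- select_samples(nm, condition = "pre_selection")
  if (!length(post)) fail("data error: no post-co-culture samples in manifest")
  if (!length(ref)) fail("data error: no pre-selection samples in manifest")

  pca <- pca_samples(nm, n_components = min(4, ncol(nm$values)))
  clust <- correlation_clustering(nm)
  et <- enrichment_table(nm, lib, post, ref, fdr = cfg$fdr)
  calls <- call_enriched(et)
  it <- interaction_analysis(et, alpha = cfg$alpha)

  write_csv_out(data.frame(pca$coords,
                           check.names = FALSE), out_dir, "qc_pca.csv")
  write_csv_out(data.frame(sample_id = clust$samples$sample_id,
                           cluster_k2 = stats::cutree(clust$hclust, k = 2)),
                out_dir, "qc_clusters.csv")
  write_csv_out(as.data.frame(et), out_dir, "enrichment.csv")
  write_csv_out(gene_pair_summary(et), out_dir, "gene_pairs.csv")
  write_csv_out(as.data.frame(it), out_dir, "interactions.csv")
  # scatter data mirroring the adjusted-p vs studentized-residual display
  write_csv_out(data.frame(gene1 = it$gene1, gene2 = it$gene2, t = it$t,
                           p_bonferroni = it$p_bonferroni, class = it$class),
                out_dir, "interaction_scatter.csv")

  list(normalized = nm, pca = pca, clustering = clust, enrichment = et,
       calls = calls, interactions = it)
}

run_metadata <- function(cfg, out_dir, extra = list()) {
  cfg_json <- jsonlite::toJSON(list(
    pos1_genes = cfg$pos1_genes, pos2_genes = cfg$pos2_genes,
    guides_per_gene = cfg$guides_per_gene, ntc_per_position = cfg$ntc_per_position,
    design = unclass(cfg$design)[c("moi", "coverage", "et_ratios", "replicates",
                                   "screens", "depth")],
    pseudocount = cfg$pseudocount, fdr = cfg$fdr, alpha = cfg$alpha,
    watch_genes = cfg$watch_genes, seed = cfg$seed
  ), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  meta <- c(list(package = "dkoscreen",
                 version = as.character(utils::packageVersion("dkoscreen")),
                 seed = cfg$seed,
                 config = jsonlite::fromJSON(cfg_json),
                 config_md5 = unname(tools::md5sum(tf))),
            extra)
  unlink(tf)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the simulated end-to-end demonstration pipeline
#'
#' Builds the library from the config, simulates the screen with the planted
#' truth, runs normalization, QC, enrichment and interaction calling, and
#' writes the full bundle (library, counts, manifest, truth, QC, enrichment,
#' interaction and truth-versus-called confusion CSVs plus metadata JSON)
#' into `out_dir`. Deterministic: the same config and seed reproduce every
#' CSV byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()]; default [demo_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Invisible list with the in-memory results (`lib`, `screen`,
#'   `enrichment`, `interactions`, `confusion`, ...).
#' @export
run_demo <- function(out_dir, config = demo_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lib <- build_dual_library(config$pos1_genes, config$pos2_genes,
                            guides_per_pos1_gene = config$guides_per_gene,
                            guides_per_pos2_gene = config$guides_per_gene,
                            ntc_pos1 = config$ntc_per_position,
                            ntc_pos2 = config$ntc_per_position,
                            seed = sub_seed(config$seed, 1))
  scr <- simulate_screen(lib, config$design, config$truth, config$noise,
                         seed = sub_seed(config$seed, 2))

  write_library(lib, file.path(out_dir, "library.csv"))
  write_csv_out(data.frame(construct_id = rownames(scr$counts), scr$counts,
                           check.names = FALSE), out_dir, "counts.csv")
  write_csv_out(scr$samples, out_dir, "manifest.csv")
  write_csv_out(data.frame(gene = c(names(config$truth$beta1), names(config$truth$beta2)),
                           position = c(rep(1L, length(config$truth$beta1)),
                                        rep(2L, length(config$truth$beta2))),
                           beta = c(unname(config$truth$beta1), unname(config$truth$beta2))),
                out_dir, "truth_gene_effects.csv")
  write_csv_out(config$truth$interactions, out_dir, "truth_interactions.csv")

  res <- analyze_counts(as.count_matrix(scr), lib, config, out_dir)

  confusion <- interaction_confusion(res$interactions, config$truth)
  write_csv_out(confusion, out_dir, "confusion.csv")
  run_metadata(config, out_dir,
               extra = list(n_constructs = nrow(lib$constructs),
                            n_samples = ncol(scr$counts),
                            clipped_survival_probs = scr$clipped))
  invisible(c(list(lib = lib, screen = scr, confusion = confusion), res))
}

#' Truth-versus-called confusion table for planted interactions
#'
#' Rows are the planted classes (`additive` for gamma > 0, `subtractive` for
#' gamma < 0, `none` for unplanted pairs), columns the called classes; each
#' row sums to the number of pairs planted in that class.
#'
#' @param it An [interaction_analysis()] table.
#' @param truth The [fitness_truth()] used in simulation.
#' @return Data frame with one row per planted class.
#' @export
interaction_confusion <- function(it, truth) {
  key <- paste(it$gene1, it$gene2, sep = "\r")
  planted <- rep("none", nrow(it))
  if (nrow(truth$interactions)) {
    ikey <- paste(truth$interactions$gene1, truth$interactions$gene2, sep = "\r")
    m <- match(key, ikey)
    planted[!is.na(m)] <- ifelse(truth$interactions$gamma[m[!is.na(m)]] > 0,
                                 "additive", "subtractive")
  }
  lv <- c("additive", "subtractive", "none")
  tab <- table(factor(planted, lv), factor(it$class, lv))
  out <- data.frame(planted = rownames(tab), as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE)
  names(out) <- c("planted", paste0("called_", colnames(tab)))
  rownames(out) <- NULL
  out
}

#' Analyze user-supplied counts through the same pipeline as the demo
#'
#' @param out_dir Output directory.
#' @param counts Construct x sample integer matrix (or `count_matrix`).
#' @param manifest Sample sheet (ignored when `counts` is a `count_matrix`).
#' @param lib The `dual_library` the counts are indexed by.
#' @param config A [run_config()] supplying the analysis parameters.
#' @return Invisible list of results (same shape as [run_demo()] minus the
#'   simulation pieces).
#' @export
run_analysis <- function(out_dir, counts, manifest = NULL, lib, config) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts, manifest)
  missing_rows <- setdiff(lib$constructs$construct_id, rownames(cm$counts))
  if (length(missing_rows))
    fail("data error: counts are missing construct(s): %s",
         paste(utils::head(missing_rows, 5), collapse = ", "))
  cm$counts <- cm$counts[lib$constructs$construct_id, , drop = FALSE]
  res <- analyze_counts(cm, lib, config, out_dir)
  run_metadata(config, out_dir, extra = list(n_constructs = nrow(lib$constructs),
                                             n_samples = ncol(cm$counts)))
  invisible(res)
}
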