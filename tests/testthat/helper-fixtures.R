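# Shared fixtures, built in code at test time.

# 2 x 2 genes, 1 guide each, 1 NTC per slot: 9 constructs
toy_library <- function(seed = 11) {
  build_dual_library(c("Jak1", "Jak2"), c("Trp53", "Pten"),
                     guides_per_pos1_gene = 1, guides_per_pos2_gene = 1,
                     ntc_pos1 = 1, ntc_pos2 = 1, seed = seed)
}

# mid-sized library for counting / QC simulations
qc_library <- function(seed = 12) {
  build_dual_library(sprintf("R%02d", 1:8), sprintf("T%02d", 1:4),
                     guides_per_pos1_gene = 2, guides_per_pos2_gene = 2,
                     ntc_pos1 = 4, ntc_pos2 = 4, seed = seed)
}

# control-rich library: DNTCs dominate, giving the empirical FDR estimator
# enough resolution for small q values at modest call counts
control_rich_library <- function(seed = 13) {
  build_dual_library(c("Jak1", "Jak2", "Neu1", "Neu2"), c("Trp53", "Pten", "Apc"),
                     guides_per_pos1_gene = 2, guides_per_pos2_gene = 2,
                     ntc_pos1 = 25, ntc_pos2 = 25, seed = seed)
}

strong_truth <- function() fitness_truth(beta1 = c(Jak1 = 3, Jak2 = 3))

# strong selection matching qc_library()'s gene names
qc_strong_truth <- function() fitness_truth(beta1 = c(R01 = 3, R02 = 3))

# full-size recovery study: 61 x 19 genes, 3 guides/gene, two strong
# resistance genes and 8 planted interactions of |gamma| = 1.5 on
# otherwise-neutral slot-1 genes
recovery_truth <- function() {
  fitness_truth(
    beta1 = c(R01 = 3, R02 = 3),
    interactions = data.frame(gene1 = sprintf("R%02d", 3:10),
                              gene2 = sprintf("T%02d", 1:8),
                              gamma = rep(c(1.5, -1.5), 4))
  )
}

recovery_library <- function(seed) {
  build_dual_library(sprintf("R%02d", 1:61), sprintf("T%02d", 1:19),
                     guides_per_pos1_gene = 3, guides_per_pos2_gene = 3,
                     ntc_pos1 = 10, ntc_pos2 = 10, seed = seed)
}

recovery_design <- function() {
  screen_design(et_ratios = c(2, 5), replicates = 3, depth = 5e6, coverage = 500)
}

# run one simulated screen through scoring and interaction calling
run_interaction_study <- function(lib, design, truth, seed,
                                  noise = noise_model(), alpha = 0.001) {
  scr <- simulate_screen(lib, design, truth, noise, seed = seed)
  nm <- cpm_log_normalize(scr)
  et <- enrichment_table(nm, lib, select_samples(nm, condition = "post_coculture"),
                         "pre_selection")
  interaction_analysis(et, alpha = alpha)
}

# null titration table: both groups drawn from the same survival distribution
null_titration <- function(n_ratios = 6, reps = 3) {
  ratios <- rep(c(0.1, 0.5, 1, 2, 5, 10)[seq_len(n_ratios)], each = 2 * reps)
  data.frame(et_ratio = ratios,
             group = rep(rep(c("library", "parental"), each = reps), n_ratios),
             survival = pmin(1.5, pmax(0, stats::rnorm(length(ratios), 0.5, 0.05))))
}
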