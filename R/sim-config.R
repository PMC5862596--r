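#' Simulation configuration
#'
#' Collects every parameter of the synthetic study generator. Defaults
#' reproduce the design of the tissue study the package models: 11
#' tumor/matched-control pairs spread over four iTRAQ 4-plex sets with a
#' pooled control in channel 114 (and a pooled tumor in channel 117 of the
#' last set), two search engines with partially overlapping protein
#' detection, multiplicative log-normal reporter noise, a scale-free
#' confidence-weighted interaction network, and triplicate-injection MRM
#' runs on 10 pairs.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_patients Tumor/control pairs (default 11).
#' @param n_sets Number of 4-plex sets (default 4).
#' @param frac_up,frac_down Fractions of proteins planted up-/down-regulated;
#'   must sum to at most 1.
#' @param effect_log2fc_mean,effect_log2fc_sd Mean and SD (log2 units) of the
#'   per-patient effect magnitude for planted proteins.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise on reporter intensities and MRM peak areas; must be > 0.
#' @param peptides_per_protein_mean Mean peptides per protein
#'   (1 + Poisson(mean - 1), so always at least one).
#' @param psms_per_peptide_mean Mean PSMs per peptide per set
#'   (1 + Poisson(mean - 1)).
#' @param unique_peptide_prob Probability a peptide is protein-unique (only
#'   unique peptides count toward the >= 2 unique peptides rule).
#' @param engine_detect_prob Marginal probability each engine detects a
#'   protein.
#' @param engine_overlap_corr Correlation in `[0, 1]` of the latent
#'   detectability shared by the two engines; higher values give more
#'   overlap between engine-specific protein lists.
#' @param set_detect_prob Probability a detected protein is observed in any
#'   given 4-plex set (drives the "at least 3 of 4 sets" filter).
#' @param trend_consistency Probability a patient's fold change agrees in
#'   sign with the protein's planted direction.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   protein abundance (arbitrary intensity units).
#' @param network_nodes Number of nodes in the simulated PPI network; must be
#'   at least `n_proteins`.
#' @param network_edges_per_node Edges attached per node by the
#'   preferential-attachment generator.
#' @param n_hubs Number of planted hub nodes wired to many differential
#'   proteins (0 disables hub planting).
#' @param hub_prior_fraction Fraction of differential proteins each planted
#'   hub connects to.
#' @param mrm_n_pairs Tumor/control pairs measured by MRM (default 10, a
#'   subset of the 11 discovery pairs).
#' @param seed Integer seed; identical configurations give bit-identical
#'   outputs.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_proteins = 50, seed = 7)
#' cfg$frac_up
#' @export
sim_config <- function(n_proteins = 200L,
                       n_patients = 11L,
                       n_sets = 4L,
                       frac_up = 0.1,
                       frac_down = 0.1,
                       effect_log2fc_mean = 1,
                       effect_log2fc_sd = 0.2,
                       noise_cv = 0.2,
                       peptides_per_protein_mean = 5,
                       psms_per_peptide_mean = 3,
                       unique_peptide_prob = 0.95,
                       engine_detect_prob = 0.995,
                       engine_overlap_corr = 0.5,
                       set_detect_prob = 0.99,
                       trend_consistency = 0.9,
                       baseline_meanlog = log(1e5),
                       baseline_sdlog = 1,
                       network_nodes = 400L,
                       network_edges_per_node = 2L,
                       n_hubs = 0L,
                       hub_prior_fraction = 0.6,
                       mrm_n_pairs = 10L,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_patients = as.integer(n_patients),
    n_sets = as.integer(n_sets),
    frac_up = frac_up,
    frac_down = frac_down,
    effect_log2fc_mean = effect_log2fc_mean,
    effect_log2fc_sd = effect_log2fc_sd,
    noise_cv = noise_cv,
    peptides_per_protein_mean = peptides_per_protein_mean,
    psms_per_peptide_mean = psms_per_peptide_mean,
    unique_peptide_prob = unique_peptide_prob,
    engine_detect_prob = engine_detect_prob,
    engine_overlap_corr = engine_overlap_corr,
    set_detect_prob = set_detect_prob,
    trend_consistency = trend_consistency,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    network_nodes = as.integer(network_nodes),
    network_edges_per_node = as.integer(network_edges_per_node),
    n_hubs = as.integer(n_hubs),
    hub_prior_fraction = hub_prior_fraction,
    mrm_n_pairs = as.integer(mrm_n_pairs),
    seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1L) {
    stop("configuration error: n_proteins must be positive", call. = FALSE)
  }
  probs <- c(unique_peptide_prob = cfg$unique_peptide_prob,
             engine_detect_prob = cfg$engine_detect_prob,
             engine_overlap_corr = cfg$engine_overlap_corr,
             set_detect_prob = cfg$set_detect_prob,
             trend_consistency = cfg$trend_consistency,
             frac_up = cfg$frac_up, frac_down = cfg$frac_down,
             hub_prior_fraction = cfg$hub_prior_fraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop(sprintf("configuration error: %s must lie in [0, 1]",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (cfg$frac_up + cfg$frac_down > 1) {
    stop("configuration error: frac_up + frac_down must not exceed 1",
         call. = FALSE)
  }
  if (cfg$noise_cv <= 0) {
    stop("configuration error: noise_cv must be > 0", call. = FALSE)
  }
  if (cfg$peptides_per_protein_mean < 1) {
    stop("configuration error: peptides_per_protein_mean must be >= 1",
         call. = FALSE)
  }
  if (cfg$mrm_n_pairs > cfg$n_patients) {
    stop("configuration error: mrm_n_pairs cannot exceed n_patients",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d proteins, %d patients in %d sets, %.0f%% up / %.0f%% down\n",
    x$n_proteins, x$n_patients, x$n_sets, 100 * x$frac_up, 100 * x$frac_down))
  cat(sprintf("  effect log2FC ~ N(%.2f, %.2f), noise CV %.2f, trend consistency %.2f\n",
              x$effect_log2fc_mean, x$effect_log2fc_sd, x$noise_cv,
              x$trend_consistency))
  cat(sprintf("  network: %d nodes, %d edges/node, %d planted hub(s); seed %d\n",
              x$network_nodes, x$network_edges_per_node, x$n_hubs, x$seed))
  invisible(x)
}

# log-normal sdlog giving a multiplicative CV
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# stage-specific RNG offsets so each simulator is reproducible on its own
.sim_seed_offsets <- c(truth = 0L, psm = 1L, network = 2L,
                       refs = 3L, mrm = 4L)

sim_stage_seed <- function(cfg, stage) {
  cfg$seed + .sim_seed_offsets[[stage]]
}
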