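#' Simulate ground-truth protein effects
#'
#' Plants `round(frac_up * n_proteins)` up-regulated and
#' `round(frac_down * n_proteins)` down-regulated proteins; the rest are
#' null. For a planted protein each patient's true log2 fold change has
#' magnitude `|N(effect_log2fc_mean, effect_log2fc_sd)|` and agrees in sign
#' with the protein's direction with probability `trend_consistency`
#' (mimicking inter-patient heterogeneity). Null proteins have log2 fold
#' change exactly zero for every patient. Engine detectability is a shared
#' latent Gaussian thresholded per engine, giving two overlapping detection
#' lists whose overlap grows with `engine_overlap_corr`.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: a list with `proteins` (data
#'   frame: `protein_id`, `direction`, `in_engine1`, `in_engine2`,
#'   `panel_member`) and `log2fc` (proteins x patients matrix of true per-
#'   patient log2 fold changes).
#' @examples
#' truth <- simulate_truth(sim_config(n_proteins = 20, seed = 1))
#' table(truth$proteins$direction)
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_stage_seed(config, "truth"))
  n <- config$n_proteins
  np <- config$n_patients
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  direction <- rep("null", n)
  if (n_up > 0) direction[seq_len(n_up)] <- "up"
  if (n_down > 0) direction[n_up + seq_len(n_down)] <- "down"
  protein_id <- sprintf("P%04d", seq_len(n))
  patients <- sprintf("patient_%02d", seq_len(np))

  lfc <- matrix(0, nrow = n, ncol = np, dimnames = list(protein_id, patients))
  eff <- which(direction != "null")
  if (length(eff)) {
    sign_dir <- ifelse(direction[eff] == "up", 1, -1)
    mag <- matrix(abs(stats::rnorm(length(eff) * np,
                                   mean = config$effect_log2fc_mean,
                                   sd = config$effect_log2fc_sd)),
                  nrow = length(eff))
    agree <- matrix(stats::runif(length(eff) * np) < config$trend_consistency,
                    nrow = length(eff))
    # discordant patients show a weak opposite change, not an equally strong
    # one: their magnitude is attenuated by a uniform factor
    atten <- matrix(stats::runif(length(eff) * np), nrow = length(eff))
    lfc[eff, ] <- mag * ifelse(agree, 1, -atten) * sign_dir
  }

  # shared latent detectability, thresholded per engine
  z1 <- stats::rnorm(n)
  rho <- config$engine_overlap_corr
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  thr <- stats::qnorm(config$engine_detect_prob)
  proteins <- data.frame(
    protein_id = protein_id,
    direction = direction,
    in_engine1 = z1 < thr,
    in_engine2 = z2 < thr,
    panel_member = FALSE,
    stringsAsFactors = FALSE)
  ground_truth(proteins, lfc)
}

#' Construct a ground-truth object
#'
#' Low-level constructor used by [simulate_truth()] and by tests that plant
#' explicit effect sizes (for example the fold changes of a validated
#' biomarker panel).
#'
#' @param proteins Data frame with at least `protein_id` and `direction`
#'   (`"up"`, `"down"` or `"null"`); `in_engine1`, `in_engine2` and
#'   `panel_member` are filled with defaults when missing.
#' @param log2fc Numeric matrix (proteins x patients) of true per-patient
#'   log2 fold changes, rownames matching `protein_id`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(proteins, log2fc) {
  stopifnot(is.data.frame(proteins), is.matrix(log2fc),
            all(c("protein_id", "direction") %in% names(proteins)),
            nrow(log2fc) == nrow(proteins))
  if (is.null(rownames(log2fc))) rownames(log2fc) <- proteins$protein_id
  stopifnot(identical(rownames(log2fc), proteins$protein_id))
  if (is.null(colnames(log2fc))) {
    colnames(log2fc) <- sprintf("patient_%02d", seq_len(ncol(log2fc)))
  }
  if (is.null(proteins$in_engine1)) proteins$in_engine1 <- TRUE
  if (is.null(proteins$in_engine2)) proteins$in_engine2 <- TRUE
  if (is.null(proteins$panel_member)) proteins$panel_member <- FALSE
  stopifnot(all(proteins$direction %in% c("up", "down", "null")))
  structure(list(proteins = proteins, log2fc = log2fc), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(factor(x$proteins$direction, levels = c("up", "down", "null")))
  cat(sprintf("Ground truth: %d proteins (%d up, %d down, %d null), %d patients\n",
              nrow(x$proteins), tab[["up"]], tab[["down"]], tab[["null"]],
              ncol(x$log2fc)))
  invisible(x)
}

# deterministic tryptic-looking peptide sequences
random_peptides <- function(n, min_len = 7L, max_len = 14L) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  vapply(lens, function(L) {
    paste0(paste(sample(aa, L - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

#' Simulate PSM-level reporter-intensity tables
#'
#' Generates peptide-spectrum-match rows for every engine and 4-plex set.
#' Reporter intensities follow the pooled-reference model: channel 114
#' carries the control pool at the protein's baseline abundance; a patient
#' channel carries baseline x that patient's true fold change; the pooled
#' tumor channel (if present) carries baseline x the geometric mean of all
#' patients' fold changes. Every intensity receives independent
#' multiplicative log-normal noise with coefficient of variation
#' `noise_cv`. A protein only yields rows for engines it is detected by
#' (`in_engine*`) and, per set, with probability `set_detect_prob`.
#'
#' @param truth A [ground_truth()] object.
#' @param design A [plex_design()] covering the same patients as `truth`.
#' @param config The [sim_config()] used to build `truth`.
#' @return A data frame with one row per PSM: `protein_id`, `peptide_seq`,
#'   `is_unique`, `set_id`, `engine`, `i114`, `i115`, `i116`, `i117`.
#' @export
simulate_psm_tables <- function(truth, design, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  design <- validate_plex_design(design)
  patients <- design_patients(design)
  missing <- setdiff(patients, colnames(truth$log2fc))
  if (length(missing)) {
    stop(sprintf("design error: design patients absent from truth: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  set.seed(sim_stage_seed(config, "psm"))
  n <- nrow(truth$proteins)
  sdlog <- lognormal_sdlog(config$noise_cv)

  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  n_pep <- 1L + stats::rpois(n, max(config$peptides_per_protein_mean - 1, 0))
  pep_seq <- random_peptides(sum(n_pep))
  pep_protein <- rep(seq_len(n), n_pep)
  pep_unique <- stats::runif(sum(n_pep)) < config$unique_peptide_prob
  pep_response <- stats::rlnorm(sum(n_pep), 0, 0.5)

  pooled_tumor_fc <- 2^rowMeans(truth$log2fc)  # geometric mean on ratio scale
  in_engine <- cbind(truth$proteins$in_engine1, truth$proteins$in_engine2)
  sets <- sort(unique(design$set_id))
  engines <- c("engine1", "engine2")

  out <- vector("list", length(sets) * length(engines))
  k <- 0L
  for (e in seq_along(engines)) {
    for (s in sets) {
      detected <- in_engine[, e] & (stats::runif(n) < config$set_detect_prob)
      pep_keep <- which(detected[pep_protein])
      if (!length(pep_keep)) next
      n_psm <- 1L + stats::rpois(length(pep_keep),
                                 max(config$psms_per_peptide_mean - 1, 0))
      row_pep <- rep(pep_keep, n_psm)
      row_prot <- pep_protein[row_pep]
      base_int <- baseline[row_prot] * pep_response[row_pep]
      dsub <- design[design$set_id == s, ]
      intens <- matrix(NA_real_, nrow = length(row_pep), ncol = 4,
                       dimnames = list(NULL, c("i114", "i115", "i116", "i117")))
      for (j in seq_len(nrow(dsub))) {
        ch <- dsub$channel[j]
        fac <- switch(dsub$role[j],
          pooled_control = 1,
          pooled_tumor = pooled_tumor_fc[row_prot],
          patient = 2^truth$log2fc[cbind(row_prot,
                     match(dsub$patient_id[j], colnames(truth$log2fc)))])
        noise <- stats::rlnorm(length(row_pep), -sdlog^2 / 2, sdlog)
        intens[, paste0("i", ch)] <- base_int * fac * noise
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        protein_id = truth$proteins$protein_id[row_prot],
        peptide_seq = pep_seq[row_pep],
        is_unique = pep_unique[row_pep],
        set_id = s,
        engine = engines[e],
        intens,
        stringsAsFactors = FALSE)
    }
  }
  psms <- do.call(rbind, out[seq_len(k)])
  rownames(psms) <- NULL
  psms
}

#' Simulate a confidence-weighted PPI network
#'
#' Builds a scale-free backbone by preferential attachment
#' (`network_edges_per_node` edges per incoming node), assigns uniform
#' (0.5, 1] edge confidences, and maps the ground-truth proteins onto
#' randomly chosen nodes; the remaining nodes are background interactors.
#' Optionally plants `n_hubs` hub nodes, each wired with high-confidence
#' edges to `hub_prior_fraction` of the differential (non-null) proteins —
#' emulating highly connected neighbors such as transcription factors.
#'
#' @param config A [sim_config()]; `network_nodes` must be at least the
#'   number of truth proteins.
#' @param truth A [ground_truth()] object.
#' @return An object of class `ppi_network`: list with `nodes` (character)
#'   and `edges` (data frame `node_a`, `node_b`, `confidence`), plus a
#'   `hubs` character vector attribute of planted hub ids.
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  n_prot <- nrow(truth$proteins)
  if (config$network_nodes < n_prot) {
    stop("configuration error: network_nodes must be >= number of truth proteins",
         call. = FALSE)
  }
  set.seed(sim_stage_seed(config, "network"))
  g <- igraph::sample_pa(config$network_nodes,
                         m = config$network_edges_per_node,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- sprintf("N%04d", seq_len(config$network_nodes))
  slots <- sample(config$network_nodes, n_prot)
  nodes[slots] <- truth$proteins$protein_id
  edges <- data.frame(node_a = nodes[el[, 1]], node_b = nodes[el[, 2]],
                      confidence = stats::runif(nrow(el), 0.5, 1),
                      stringsAsFactors = FALSE)
  hubs <- character(0)
  if (config$n_hubs > 0L) {
    de <- truth$proteins$protein_id[truth$proteins$direction != "null"]
    n_wire <- round(config$hub_prior_fraction * length(de))
    for (h in seq_len(config$n_hubs)) {
      hub_id <- sprintf("HUB%02d", h)
      hubs <- c(hubs, hub_id)
      targets <- sample(de, n_wire)
      edges <- rbind(edges, data.frame(
        node_a = hub_id, node_b = targets,
        confidence = stats::runif(n_wire, 0.9, 1),
        stringsAsFactors = FALSE))
    }
    nodes <- c(nodes, hubs)
  }
  net <- ppi_network(nodes, edges)
  attr(net, "hubs") <- hubs
  net
}

#' Construct a PPI network object
#'
#' @param nodes Character vector of node identifiers (may be omitted, in
#'   which case nodes are taken from the edge list).
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`;
#'   the graph is undirected, self-loops are rejected and confidences must
#'   lie in (0, 1].
#' @return An object of class `ppi_network`.
#' @export
ppi_network <- function(nodes = NULL, edges) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "confidence") %in% names(edges)))
  if (any(edges$node_a == edges$node_b)) {
    stop("network error: self-loops are not allowed", call. = FALSE)
  }
  if (any(edges$confidence <= 0 | edges$confidence > 1)) {
    stop("network error: edge confidences must lie in (0, 1]", call. = FALSE)
  }
  edge_nodes <- unique(c(edges$node_a, edges$node_b))
  if (is.null(nodes)) nodes <- edge_nodes
  stopifnot(all(edge_nodes %in% nodes))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Simulate external reference tables
#'
#' Emulates two kinds of published references used for concordance
#' scoring: a label-free fold-change reference (CPTAC-like, tumor/normal
#' ratio per protein) and a categorical immunohistochemistry reference
#' (HPA-like fractions of the population scored high / medium / low /
#' not detected). Fold changes track the true mean effect with log-normal
#' scatter; differential proteins get high+medium mass on the side of
#' their direction.
#'
#' @param truth A [ground_truth()] object.
#' @param config The matching [sim_config()].
#' @return Data frame: `protein_id`, `cptac_fc`, `hpa_high`, `hpa_medium`,
#'   `hpa_low`, `hpa_not_detected` (fractions summing to 1).
#' @export
simulate_external_refs <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(sim_stage_seed(config, "refs"))
  n <- nrow(truth$proteins)
  mean_lfc <- rowMeans(truth$log2fc)
  cptac_fc <- 2^(mean_lfc + stats::rnorm(n, 0, 0.3))
  dir <- truth$proteins$direction
  hm <- ifelse(dir == "up", stats::runif(n, 0.55, 0.95),
        ifelse(dir == "down", stats::runif(n, 0.05, 0.45),
               stats::runif(n, 0.2, 0.8)))
  high <- hm * stats::runif(n, 0.3, 0.7)
  medium <- hm - high
  rest <- 1 - hm
  low <- rest * stats::runif(n, 0.3, 0.7)
  data.frame(protein_id = truth$proteins$protein_id,
             cptac_fc = cptac_fc,
             hpa_high = high, hpa_medium = medium,
             hpa_low = low, hpa_not_detected = rest - low,
             stringsAsFactors = FALSE)
}

#' Build a transition panel specification
#'
#' Convenience generator for an MRM panel table: `n_peptides` peptides per
#' protein and `n_transitions` transitions per peptide, with scheduled
#' retention times spread over the gradient.
#'
#' @param protein_ids Character vector of panel proteins.
#' @param n_peptides Peptides per protein (>= 3 for a valid method).
#' @param n_transitions Transitions per peptide (>= 3 for a valid method).
#' @param rt_range Numeric length-2: retention-time range in minutes.
#' @return Data frame: `protein_id`, `peptide_seq`, `transition_id`,
#'   `expected_rt`.
#' @export
make_panel_spec <- function(protein_ids, n_peptides = 3L, n_transitions = 3L,
                            rt_range = c(2, 16)) {
  rows <- list()
  for (p in protein_ids) {
    for (j in seq_len(n_peptides)) {
      pep <- sprintf("%s_pep%02d", p, j)
      rt <- rt_range[1] + (rt_range[2] - rt_range[1]) *
        ((match(p, protein_ids) - 1) * n_peptides + j) /
        (length(protein_ids) * n_peptides + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, peptide_seq = pep,
        transition_id = sprintf("%s_t%d", pep, seq_len(n_transitions)),
        expected_rt = rt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate MRM transition peak areas
#'
#' Generates triplicate-injection peak areas for `mrm_n_pairs`
#' tumor/matched-control pairs. A transition's area is the product of the
#' protein's abundance in that sample (baseline, times the patient's true
#' fold change in tumors), a peptide response factor, a transition share
#' factor, and multiplicative log-normal noise (CV `noise_cv`).
#'
#' @param truth A [ground_truth()] object; every panel protein must be in
#'   it.
#' @param panel_spec Transition table as from [make_panel_spec()].
#' @param config The matching [sim_config()].
#' @return A `PeakAreaTable` data frame: `protein_id`, `peptide_seq`,
#'   `transition_id`, `sample_id`, `condition` (`tumor`/`control`),
#'   `patient_id`, `replicate` (1-3), `area`.
#' @export
simulate_mrm <- function(truth, panel_spec, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  absent <- setdiff(unique(panel_spec$protein_id), truth$proteins$protein_id)
  if (length(absent)) {
    stop(sprintf("specification error: panel proteins absent from truth: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  set.seed(sim_stage_seed(config, "mrm"))
  sdlog <- lognormal_sdlog(config$noise_cv)
  patients <- colnames(truth$log2fc)[seq_len(config$mrm_n_pairs)]

  prot_ids <- unique(panel_spec$protein_id)
  base <- stats::rlnorm(length(prot_ids), config$baseline_meanlog,
                        config$baseline_sdlog)
  names(base) <- prot_ids
  peps <- unique(panel_spec[, c("protein_id", "peptide_seq")])
  pep_resp <- stats::rlnorm(nrow(peps), 0, 0.5)
  names(pep_resp) <- peps$peptide_seq
  trans_share <- stats::rlnorm(nrow(panel_spec), 0, 0.3)
  names(trans_share) <- panel_spec$transition_id

  grid <- expand.grid(row = seq_len(nrow(panel_spec)),
                      patient = patients,
                      condition = c("tumor", "control"),
                      replicate = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prot <- panel_spec$protein_id[grid$row]
  fc <- ifelse(grid$condition == "tumor",
               2^truth$log2fc[cbind(match(prot, rownames(truth$log2fc)),
                                    match(grid$patient, colnames(truth$log2fc)))],
               1)
  area <- base[prot] *
    pep_resp[panel_spec$peptide_seq[grid$row]] *
    trans_share[panel_spec$transition_id[grid$row]] *
    fc * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  out <- data.frame(
    protein_id = prot,
    peptide_seq = panel_spec$peptide_seq[grid$row],
    transition_id = panel_spec$transition_id[grid$row],
    sample_id = paste0(ifelse(grid$condition == "tumor", "T", "C"),
                       sub("patient_", "", grid$patient)),
    condition = grid$condition,
    patient_id = grid$patient,
    replicate = grid$replicate,
    area = unname(area),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
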