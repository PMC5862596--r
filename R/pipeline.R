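#' Assemble a pipeline configuration
#'
#' Bundles all stage thresholds with the synthetic-study parameters. The
#' threshold defaults are the study's published values: average fold
#' change 1.5 (and its reciprocal for down-regulation), detection in at
#' least 3 of 4 sets, the same trend in at least 7 of 11 patients,
#' pooled/per-protein top-50 propagation lists cut to a final top-20, and
#' MRM significance at fold change >= 1.5 with p <= 0.05.
#'
#' @param sim A [sim_config()] describing the synthetic study.
#' @param fc_threshold Consensus average fold-change cut-off (default 1.5).
#' @param min_sets,total_sets Multi-set detection rule (default 3 of 4).
#' @param min_trend Patients that must share the trend (default 7).
#' @param alpha Propagation smoothing weight in (0, 1) (default 0.8).
#' @param k Propagation top-list size (default 50).
#' @param final_k Final neighbor report size (default 20).
#' @param mrm_fc,mrm_alpha MRM significance rule (default 1.5, 0.05).
#' @param average Fold-change averaging rule (`"geometric"` default).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            fc_threshold = 1.5,
                            min_sets = 3L, total_sets = 4L,
                            min_trend = 7L,
                            alpha = 0.8, k = 50L, final_k = 20L,
                            mrm_fc = 1.5, mrm_alpha = 0.05,
                            average = "geometric") {
  stopifnot(inherits(sim, "sim_config"))
  if (min_trend > sim$n_patients) {
    stop("configuration error: min_trend cannot exceed n_patients",
         call. = FALSE)
  }
  if (min_sets > total_sets) {
    stop("configuration error: min_sets cannot exceed total_sets",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(sim = sim, fc_threshold = fc_threshold,
                 min_sets = as.integer(min_sets),
                 total_sets = as.integer(total_sets),
                 min_trend = as.integer(min_trend),
                 alpha = alpha, k = as.integer(k),
                 final_k = as.integer(final_k),
                 mrm_fc = mrm_fc, mrm_alpha = mrm_alpha,
                 average = average),
            class = "pipeline_config")
}

#' Run the full synthetic study end to end
#'
#' Simulates the study (truth, PSM tables, network, external references,
#' MRM areas), then runs quantitation, the per-engine consensus filter
#' chains, the engine intersection and union, external concordance,
#' network propagation of the union list (pooled and per direction), and
#' MRM panel validation. All randomness derives from `config$sim$seed`,
#' so identical configurations give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param panel_size Number of top consensus proteins carried into the
#'   MRM panel (default 9).
#' @param n_null_panel Additional null proteins added to the MRM panel as
#'   negative controls (default 5).
#' @return Object of class `pipeline_run`: list with `truth`, `design`,
#'   `quants`, per-engine `consensus` (tables + waterfalls),
#'   `intersection`, `union`, `concordance`, `neighbor_reports` (pooled /
#'   up / down), `mrm` (method, abundances, results) and `summary`
#'   counts.
#' @export
run_pipeline <- function(config, panel_size = 9L, n_null_panel = 5L) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  truth <- simulate_truth(sim)
  design <- plex_design(sim$n_patients, sim$n_sets)
  psms <- simulate_psm_tables(truth, design, sim)
  quants <- aggregate_protein_ratios(psms)

  consensus <- list()
  for (e in c("engine1", "engine2")) {
    consensus[[e]] <- consensus_filter(
      quants[quants$engine == e, , drop = FALSE], design,
      fc_threshold = config$fc_threshold, min_sets = config$min_sets,
      total_sets = config$total_sets, min_agree = config$min_trend,
      average = config$average)
  }
  inter <- intersect_engines(consensus$engine1$table, consensus$engine2$table)
  uni <- combine_union(consensus$engine1$table, consensus$engine2$table)

  refs <- simulate_external_refs(truth, sim)
  concord <- concordance_external(inter, refs)

  net <- simulate_network(sim, truth)
  priors_all <- uni$protein_id
  neighbor_reports <- list()
  if (length(priors_all)) {
    neighbor_reports$pooled <- propagation_report(
      net, priors_all, k = config$k, final_k = config$final_k,
      alpha = config$alpha)
    for (d in c("up", "down")) {
      pr <- uni$protein_id[uni$direction == d]
      if (length(pr)) {
        neighbor_reports[[d]] <- propagation_report(
          net, pr, k = config$k, final_k = config$final_k,
          alpha = config$alpha)
      }
    }
  }

  # MRM panel: strongest consensus proteins plus null negative controls
  mrm <- NULL
  if (nrow(inter)) {
    ranked <- inter[order(-abs(log(inter$avg_fc))), ]
    panel_ids <- utils::head(ranked$protein_id, panel_size)
    nulls <- truth$proteins$protein_id[truth$proteins$direction == "null"]
    panel_ids <- c(panel_ids, utils::head(nulls, n_null_panel))
    truth$proteins$panel_member <-
      truth$proteins$protein_id %in% panel_ids
    spec <- make_panel_spec(panel_ids)
    method <- build_method(spec)
    areas <- simulate_mrm(truth, spec, sim)
    abund <- rollup_protein_abundance(areas, method)
    results <- test_dysregulation(abund, fc_threshold = config$mrm_fc,
                                  alpha = config$mrm_alpha)
    mrm <- list(panel = panel_ids, method = method, abundances = abund,
                results = results)
  }

  summary_counts <- rbind(
    engine1 = consensus$engine1$waterfall,
    engine2 = consensus$engine2$waterfall)
  structure(list(config = config, truth = truth, design = design,
                 quants = quants, consensus = consensus,
                 intersection = inter, union = uni,
                 concordance = concord, network = net,
                 neighbor_reports = neighbor_reports, mrm = mrm,
                 summary = list(
                   waterfall = summary_counts,
                   n_intersection = nrow(inter),
                   n_union = nrow(uni),
                   n_conflicts = attr(uni, "n_conflicts"),
                   n_concordant = attr(concord, "n_concordant_all"))),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Synthetic study pipeline run\n")
  cat(sprintf("  proteins simulated: %d (%d patients, %d sets; seed %d)\n",
              x$config$sim$n_proteins, x$config$sim$n_patients,
              x$config$sim$n_sets, x$config$sim$seed))
  cat("  consensus waterfall (identified -> >=", x$config$min_sets,
      "sets -> fold change -> trend):\n")
  wf <- x$summary$waterfall
  for (e in rownames(wf)) {
    cat(sprintf("    %s: %s\n", e, paste(wf[e, ], collapse = " -> ")))
  }
  cat(sprintf("  engine intersection: %d proteins; union: %d (%d direction conflict(s))\n",
              x$summary$n_intersection, x$summary$n_union,
              x$summary$n_conflicts))
  cat(sprintf("  concordant with all external references: %d\n",
              x$summary$n_concordant))
  if (!is.null(x$neighbor_reports$pooled)) {
    cat(sprintf("  propagation: top-%d neighbor report computed (pooled%s)\n",
                x$config$final_k,
                if (length(x$neighbor_reports) > 1) " + per direction" else ""))
  }
  if (!is.null(x$mrm)) {
    cat(sprintf("  MRM: %d-protein panel, %d significant\n",
                length(x$mrm$panel), sum(x$mrm$results$significant)))
  }
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  print(object)
  if (!is.null(object$mrm)) {
    cat("\nMRM panel calls:\n")
    print.data.frame(object$mrm$results[, c("protein_id", "log2fc",
                                            "p_value", "significant")],
                     row.names = FALSE, digits = 3)
  }
  invisible(object$summary)
}
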