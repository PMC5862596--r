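#' Build an MRM method from a panel specification
#'
#' Validates and assembles the scheduled transition list for a
#' multiple-reaction-monitoring assay: every panel protein must contribute
#' at least 3 peptides and every peptide at least 3 transitions, and
#' transition ids must be unique. Dwell and pause times are stored as
#' method metadata.
#'
#' @param panel_spec Data frame with columns `protein_id`, `peptide_seq`,
#'   `transition_id` and optionally `expected_rt` (minutes).
#' @param rt_window Scheduling half-width in minutes (default 1, i.e.
#'   +/- 1 min around the expected retention time).
#' @param dwell_time,pause_time Per-transition dwell and pause, seconds.
#' @return Object of class `mrm_method`: list with `transitions` (the
#'   validated table plus `rt_window`), `n_transitions`, `dwell_time`,
#'   `pause_time`.
#' @examples
#' spec <- make_panel_spec("P0001")
#' build_method(spec)$n_transitions  # 3 peptides x 3 transitions
#' @export
build_method <- function(panel_spec, rt_window = 1, dwell_time = 0.005,
                         pause_time = 0.003) {
  stopifnot(is.data.frame(panel_spec),
            all(c("protein_id", "peptide_seq", "transition_id") %in%
                  names(panel_spec)))
  if (rt_window <= 0) {
    stop("validation error: rt_window must be positive", call. = FALSE)
  }
  dup <- unique(panel_spec$transition_id[duplicated(panel_spec$transition_id)])
  if (length(dup)) {
    stop(sprintf("validation error: duplicate transition id(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  pep_per_prot <- tapply(panel_spec$peptide_seq, panel_spec$protein_id,
                         function(x) length(unique(x)))
  bad_prot <- names(pep_per_prot)[pep_per_prot < 3]
  if (length(bad_prot)) {
    stop(sprintf("validation error: protein(s) with fewer than 3 peptides: %s",
                 paste(bad_prot, collapse = ", ")), call. = FALSE)
  }
  trans_per_pep <- tapply(panel_spec$transition_id, panel_spec$peptide_seq,
                          length)
  bad_pep <- names(trans_per_pep)[trans_per_pep < 3]
  if (length(bad_pep)) {
    stop(sprintf("validation error: peptide(s) with fewer than 3 transitions: %s",
                 paste(bad_pep, collapse = ", ")), call. = FALSE)
  }
  transitions <- panel_spec
  transitions$rt_window <- rt_window
  structure(list(transitions = transitions,
                 n_transitions = nrow(transitions),
                 dwell_time = dwell_time,
                 pause_time = pause_time),
            class = "mrm_method")
}

#' @export
print.mrm_method <- function(x, ...) {
  cat(sprintf(
    "MRM method: %d transitions (%d peptides, %d proteins); dwell %.3f s, pause %.3f s, RT window +/- %g min\n",
    x$n_transitions, length(unique(x$transitions$peptide_seq)),
    length(unique(x$transitions$protein_id)), x$dwell_time, x$pause_time,
    x$transitions$rt_window[1]))
  invisible(x)
}

#' Roll transition peak areas up to protein abundances
#'
#' Replicate injections are averaged per transition and sample; a
#' peptide's abundance is the sum of its transition areas; a protein's
#' abundance in a sample is the median over its detected peptides of
#' log2(peptide abundance). Transitions with zero or missing area are
#' treated as not detected (excluded), never as zero signal; a protein
#' with no detected transitions in a sample gets a missing value.
#'
#' @param areas `PeakAreaTable` data frame (`transition_id`, `sample_id`,
#'   `condition`, `patient_id`, `replicate`, `area`) as from
#'   [simulate_mrm()].
#' @param method The [build_method()] result; all `areas` rows must
#'   reference its transitions.
#' @return Data frame with one row per protein x sample: `protein_id`,
#'   `sample_id`, `condition`, `patient_id`, `log2_abundance`,
#'   `n_peptides_detected`, `n_transitions_detected`.
#' @export
rollup_protein_abundance <- function(areas, method) {
  stopifnot(inherits(method, "mrm_method"))
  unknown <- setdiff(unique(areas$transition_id),
                     method$transitions$transition_id)
  if (length(unknown)) {
    stop(sprintf("unknown transition id(s) in peak areas: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  tmap <- method$transitions
  # mean over replicates per transition x sample
  key <- interaction(areas$transition_id, areas$sample_id, drop = TRUE)
  rep_mean <- tapply(areas$area, key, mean)
  meta <- areas[!duplicated(key), c("transition_id", "sample_id",
                                    "condition", "patient_id")]
  meta$mean_area <- as.numeric(rep_mean[as.character(interaction(
    meta$transition_id, meta$sample_id, drop = TRUE))])
  meta$protein_id <- tmap$protein_id[match(meta$transition_id,
                                           tmap$transition_id)]
  meta$peptide_seq <- tmap$peptide_seq[match(meta$transition_id,
                                             tmap$transition_id)]
  detected <- meta[!is.na(meta$mean_area) & meta$mean_area > 0, , drop = FALSE]
  if (nrow(detected) == 0L) {
    warning("no transition detected in any sample")
    return(data.frame(protein_id = character(0), sample_id = character(0),
                      condition = character(0), patient_id = character(0),
                      log2_abundance = numeric(0),
                      n_peptides_detected = integer(0),
                      n_transitions_detected = integer(0)))
  }

  # peptide abundance: sum of detected transition areas per sample
  pkey <- interaction(detected$peptide_seq, detected$sample_id, drop = TRUE)
  pep_sum <- tapply(detected$mean_area, pkey, sum)
  pep_n_trans <- tapply(detected$mean_area, pkey, length)
  pmeta <- detected[!duplicated(pkey), c("protein_id", "peptide_seq",
                                         "sample_id", "condition",
                                         "patient_id")]
  pk <- as.character(interaction(pmeta$peptide_seq, pmeta$sample_id,
                                 drop = TRUE))
  pmeta$abundance <- as.numeric(pep_sum[pk])
  pmeta$n_transitions <- as.integer(pep_n_trans[pk])

  # protein abundance: median over peptides of log2 abundance
  rkey <- interaction(pmeta$protein_id, pmeta$sample_id, drop = TRUE)
  rows <- lapply(split(pmeta, rkey), function(g) {
    data.frame(protein_id = g$protein_id[1],
               sample_id = g$sample_id[1],
               condition = g$condition[1],
               patient_id = g$patient_id[1],
               log2_abundance = stats::median(log2(g$abundance)),
               n_peptides_detected = nrow(g),
               n_transitions_detected = sum(g$n_transitions),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$condition, out$patient_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test tumor vs matched-control dysregulation per protein
#'
#' For each protein, pairs tumor and control log2 abundances by patient
#' and computes the mean paired difference (the log2 fold change) and a
#' two-sided paired t-test p-value. A protein is called significant when
#' its fold change is at least `fc_threshold` in either direction
#' (|log2FC| >= log2(threshold)) and p <= `alpha`; no multiple-testing
#' correction is applied. Proteins with fewer than `min_pairs` complete
#' pairs are reported untested.
#'
#' @param protein_table Output of [rollup_protein_abundance()].
#' @param fc_threshold Ratio-scale fold-change cut-off (default 1.5).
#' @param alpha Significance level for the paired test (default 0.05).
#' @param min_pairs Minimum complete tumor/control pairs (default 3).
#' @return Object of class `mrm_results`: data frame `protein_id`,
#'   `log2fc`, `p_value`, `significant`, `direction`, `n_pairs`,
#'   `tested`, `n_peptides_detected`, `n_transitions_detected`.
#' @export
test_dysregulation <- function(protein_table, fc_threshold = 1.5,
                               alpha = 0.05, min_pairs = 3L) {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1)
  rows <- lapply(split(protein_table, protein_table$protein_id), function(g) {
    tum <- g[g$condition == "tumor", ]
    ctl <- g[g$condition == "control", ]
    shared <- intersect(tum$patient_id, ctl$patient_id)
    diffs <- tum$log2_abundance[match(shared, tum$patient_id)] -
      ctl$log2_abundance[match(shared, ctl$patient_id)]
    diffs <- diffs[!is.na(diffs)]
    n_pairs <- length(diffs)
    npep <- max(g$n_peptides_detected)
    ntr <- max(g$n_transitions_detected)
    if (n_pairs < min_pairs) {
      return(data.frame(protein_id = g$protein_id[1], log2fc = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        direction = NA_character_, n_pairs = n_pairs,
                        tested = FALSE, n_peptides_detected = npep,
                        n_transitions_detected = ntr,
                        stringsAsFactors = FALSE))
    }
    lfc <- mean(diffs)
    p <- if (stats::sd(diffs) == 0) {
      if (lfc == 0) 1 else 0  # degenerate: all differences identical
    } else {
      stats::t.test(diffs)$p.value
    }
    sig <- abs(lfc) >= log2(fc_threshold) && p <= alpha
    data.frame(protein_id = g$protein_id[1], log2fc = lfc, p_value = p,
               significant = sig,
               direction = if (sig) ifelse(lfc > 0, "up", "down")
                           else NA_character_,
               n_pairs = n_pairs, tested = TRUE,
               n_peptides_detected = npep, n_transitions_detected = ntr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mrm_results", "data.frame")
  out
}

#' @export
print.mrm_results <- function(x, ...) {
  need <- c("tested", "significant", "direction")
  if (!all(need %in% names(x))) {  # column subset: plain data frame view
    return(print.data.frame(x, row.names = FALSE, digits = 4))
  }
  cat(sprintf("MRM results: %d proteins tested, %d significant (%d up, %d down), %d untested\n",
              sum(x$tested), sum(x$significant),
              sum(x$significant & x$direction == "up", na.rm = TRUE),
              sum(x$significant & x$direction == "down", na.rm = TRUE),
              sum(!x$tested)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
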