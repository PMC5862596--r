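#' Filter proteins by multi-set detection
#'
#' Retains proteins quantified (after the unique-peptide rule) in at least
#' `min_sets` distinct 4-plex sets, the first stage of the consensus
#' differential-expression chain.
#'
#' @param quants Quant table from [aggregate_protein_ratios()], restricted
#'   to one engine.
#' @param min_sets Minimum number of distinct sets (default 3).
#' @param total_sets Total sets in the design (default 4); `min_sets` may
#'   not exceed it.
#' @return Character vector of retained protein ids.
#' @export
filter_common_sets <- function(quants, min_sets = 3L, total_sets = 4L) {
  if (min_sets > total_sets) {
    stop("configuration error: min_sets cannot exceed total_sets",
         call. = FALSE)
  }
  if (length(unique(quants$engine)) > 1L) {
    stop("filter_common_sets expects quants from a single engine",
         call. = FALSE)
  }
  counts <- tapply(quants$set_id, quants$protein_id,
                   function(s) length(unique(s)))
  sort(names(counts)[counts >= min_sets])
}

#' Assemble per-patient protein fold changes
#'
#' Resolves every tumor channel of every set to its patient via the plex
#' design and collects, per protein and engine, one fold change per
#' patient (each patient sits in exactly one set/channel). The pooled
#' tumor channel, when present, is carried along as a QC column but never
#' contributes a patient value. The protein's average fold change is the
#' geometric mean over available patients (arithmetic mean optional).
#'
#' @param quants Quant table from [aggregate_protein_ratios()] (one or
#'   both engines).
#' @param design The [plex_design()] of the experiment.
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return Data frame with one row per protein x engine: `protein_id`,
#'   `engine`, `n_sets_detected`, `avg_fc`, `pooled_tumor_fc` (`NA` when
#'   absent), and one `fc_<patient>` column per patient in the design.
#' @export
compute_patient_fold_changes <- function(quants, design,
                                         average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  design <- validate_plex_design(design)
  patients <- design_patients(design)
  if (nrow(quants) == 0L) {
    out <- data.frame(protein_id = character(0), engine = character(0),
                      n_sets_detected = integer(0), avg_fc = numeric(0),
                      pooled_tumor_fc = numeric(0))
    for (p in patients) out[[paste0("fc_", p)]] <- numeric(0)
    return(out)
  }
  # long form: one row per protein x engine x set x tumor channel
  long <- do.call(rbind, lapply(c(115L, 116L, 117L), function(ch) {
    data.frame(protein_id = quants$protein_id, engine = quants$engine,
               set_id = quants$set_id, channel = ch,
               fc = quants[[paste0("r", ch)]], stringsAsFactors = FALSE)
  }))
  dmap <- design[design$role != "pooled_control", ]
  idx <- match(paste(long$set_id, long$channel),
               paste(dmap$set_id, dmap$channel))
  long$role <- dmap$role[idx]
  long$patient_id <- dmap$patient_id[idx]
  long <- long[!is.na(long$role), , drop = FALSE]

  key <- interaction(long$engine, long$protein_id, drop = TRUE)
  rows <- lapply(split(long, key), function(g) {
    pat <- g[g$role == "patient", , drop = FALSE]
    if (anyDuplicated(pat$patient_id)) {
      stop(sprintf("design error: patient mapped twice for protein %s",
                   g$protein_id[1]), call. = FALSE)
    }
    fc <- stats::setNames(rep(NA_real_, length(patients)), patients)
    fc[pat$patient_id] <- pat$fc
    avail <- fc[!is.na(fc)]
    avg <- if (average == "geometric") exp(mean(log(avail))) else mean(avail)
    pooled <- g$fc[g$role == "pooled_tumor"]
    out <- data.frame(protein_id = g$protein_id[1], engine = g$engine[1],
                      n_sets_detected = length(unique(g$set_id)),
                      avg_fc = avg,
                      pooled_tumor_fc = if (length(pooled)) pooled[1] else NA_real_,
                      stringsAsFactors = FALSE)
    for (p in patients) out[[paste0("fc_", p)]] <- unname(fc[p])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$engine, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter proteins by average fold change
#'
#' Retains proteins whose average fold change is at least `threshold`
#' (called up-regulated) or at most `1/threshold` (down-regulated); both
#' boundaries are inclusive. The down cut-off is the reciprocal of the up
#' cut-off because fold changes are multiplicative.
#'
#' @param table Output of [compute_patient_fold_changes()].
#' @param threshold Ratio-scale cut-off, > 1 (default 1.5).
#' @return The retained rows with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
filter_fold_change <- function(table, threshold = 1.5) {
  if (threshold <= 1) {
    stop("configuration error: fold-change threshold must exceed 1",
         call. = FALSE)
  }
  up <- table$avg_fc >= threshold
  down <- table$avg_fc <= 1 / threshold
  out <- table[up | down, , drop = FALSE]
  out$direction <- ifelse(out$avg_fc >= threshold, "up", "down")
  rownames(out) <- NULL
  out
}

#' Filter proteins by per-patient trend agreement
#'
#' Retains proteins whose per-patient fold changes agree with the assigned
#' direction in at least `min_agree` patients: fold change > 1 counts as
#' agreement for up-regulated proteins, < 1 for down-regulated; a fold
#' change of exactly 1 (or a missing patient) counts as disagreement.
#'
#' @param table Output of [filter_fold_change()] (must carry `direction`).
#' @param min_agree Minimum agreeing patients (default 7).
#' @param n_patients Patients in the design (default 11); `min_agree` may
#'   not exceed it.
#' @return The retained rows, with an added `n_trend_agree` column.
#' @export
filter_trend <- function(table, min_agree = 7L, n_patients = 11L) {
  if (min_agree > n_patients) {
    stop("configuration error: min_agree cannot exceed n_patients",
         call. = FALSE)
  }
  stopifnot("direction" %in% names(table))
  fc_cols <- grep("^fc_", names(table), value = TRUE)
  fc <- as.matrix(table[, fc_cols, drop = FALSE])
  up_agree <- rowSums(fc > 1, na.rm = TRUE)
  down_agree <- rowSums(fc < 1, na.rm = TRUE)
  agree <- ifelse(table$direction == "up", up_agree, down_agree)
  out <- table[agree >= min_agree, , drop = FALSE]
  out$n_trend_agree <- agree[agree >= min_agree]
  rownames(out) <- NULL
  out
}

#' Intersect two engines' differential lists
#'
#' Returns the proteins called differential by both search engines with
#' the same direction. Proteins present in both lists but with opposite
#' directions are excluded and reported via the `conflicts` attribute.
#'
#' @param engine1_list,engine2_list Data frames with `protein_id` and
#'   `direction` columns (any extra columns are kept from engine 1).
#' @return The engine-1 rows for agreeing proteins; attributes
#'   `conflicts` (character vector of conflicting ids) and `n_conflicts`.
#' @export
intersect_engines <- function(engine1_list, engine2_list) {
  d1 <- stats::setNames(engine1_list$direction, engine1_list$protein_id)
  d2 <- stats::setNames(engine2_list$direction, engine2_list$protein_id)
  shared <- intersect(names(d1), names(d2))
  agree <- shared[d1[shared] == d2[shared]]
  conflicts <- setdiff(shared, agree)
  if (length(conflicts)) {
    message(sprintf("intersect_engines: %d direction conflict(s) excluded: %s",
                    length(conflicts), paste(conflicts, collapse = ", ")))
  }
  out <- engine1_list[engine1_list$protein_id %in% agree, , drop = FALSE]
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  attr(out, "n_conflicts") <- length(conflicts)
  out
}

#' Combine two engines' differential lists into a union
#'
#' Returns every protein called differential by either engine, with its
#' direction taken from whichever engine(s) provide it. Proteins the two
#' engines call in opposite directions are excluded from the union and
#' reported via the `conflicts` attribute.
#'
#' @inheritParams intersect_engines
#' @return Data frame `protein_id`, `direction`, `engines` (comma-joined
#'   engine labels supporting the call); attributes `conflicts`,
#'   `n_conflicts`.
#' @export
combine_union <- function(engine1_list, engine2_list) {
  d1 <- stats::setNames(engine1_list$direction, engine1_list$protein_id)
  d2 <- stats::setNames(engine2_list$direction, engine2_list$protein_id)
  shared <- intersect(names(d1), names(d2))
  conflicts <- shared[d1[shared] != d2[shared]]
  if (length(conflicts)) {
    message(sprintf("combine_union: %d direction conflict(s) excluded: %s",
                    length(conflicts), paste(conflicts, collapse = ", ")))
  }
  ids <- setdiff(union(names(d1), names(d2)), conflicts)
  direction <- ifelse(ids %in% names(d1), d1[ids], d2[ids])
  engines <- ifelse(ids %in% shared, "engine1,engine2",
                    ifelse(ids %in% names(d1), "engine1", "engine2"))
  out <- data.frame(protein_id = ids, direction = unname(direction),
                    engines = engines, stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  attr(out, "n_conflicts") <- length(conflicts)
  out
}

#' Score concordance with external reference datasets
#'
#' Compares consensus calls against two kinds of published references: a
#' fold-change reference (concordant when the reference fold change lies
#' on the same side of 1 as the consensus call) and a categorical
#' expression reference scored as fractions of the population with
#' high / medium / low / not-detected staining (the reference calls a
#' protein up when high + medium >= 0.5, inclusive; concordant when that
#' call matches the consensus direction).
#'
#' @param consensus Data frame with `protein_id` and `direction`.
#' @param refs Reference table as from [simulate_external_refs()]; columns
#'   `cptac_fc` and/or `hpa_high` + `hpa_medium` may be missing or `NA`
#'   per protein.
#' @return The consensus rows with added columns `cptac_concordant`,
#'   `hpa_concordant` (logical, `NA` without a reference),
#'   `no_reference`, and `concordant_all` (agrees with every reference
#'   that is present); attribute `n_concordant_all`.
#' @export
concordance_external <- function(consensus, refs) {
  idx <- match(consensus$protein_id, refs$protein_id)
  cptac_fc <- if ("cptac_fc" %in% names(refs)) refs$cptac_fc[idx] else NA_real_
  hm <- if (all(c("hpa_high", "hpa_medium") %in% names(refs))) {
    refs$hpa_high[idx] + refs$hpa_medium[idx]
  } else NA_real_
  dir_sign <- ifelse(consensus$direction == "up", 1, -1)
  out <- consensus
  out$cptac_concordant <- ifelse(is.na(cptac_fc), NA,
                                 sign(log(cptac_fc)) == dir_sign)
  hpa_call <- ifelse(hm >= 0.5, "up", "down")
  out$hpa_concordant <- ifelse(is.na(hm), NA, hpa_call == consensus$direction)
  out$no_reference <- is.na(out$cptac_concordant) & is.na(out$hpa_concordant)
  has_any <- !out$no_reference
  agree_all <- rep(NA, nrow(out))
  agree_all[has_any] <-
    (is.na(out$cptac_concordant[has_any]) | out$cptac_concordant[has_any]) &
    (is.na(out$hpa_concordant[has_any]) | out$hpa_concordant[has_any])
  out$concordant_all <- agree_all
  attr(out, "n_concordant_all") <- sum(agree_all, na.rm = TRUE)
  out
}

#' Run the full consensus filter chain for one engine
#'
#' Applies, in order: multi-set detection, per-patient fold-change
#' assembly, the average fold-change cut-off, and the per-patient trend
#' filter, recording the count surviving each stage (the "waterfall").
#'
#' @param quants Quant table for a single engine.
#' @param design The [plex_design()].
#' @param fc_threshold Average fold-change cut-off (default 1.5).
#' @param min_sets Minimum sets detected (default 3).
#' @param total_sets Total sets (default 4).
#' @param min_agree Minimum agreeing patients (default 7).
#' @param average Averaging rule for [compute_patient_fold_changes()].
#' @return List with `table` (final per-protein rows incl. `direction`),
#'   and `waterfall`, a named integer vector: `identified`,
#'   `common_sets`, `fold_change`, `trend`.
#' @export
consensus_filter <- function(quants, design, fc_threshold = 1.5,
                             min_sets = 3L, total_sets = 4L, min_agree = 7L,
                             average = "geometric") {
  n_identified <- length(unique(quants$protein_id))
  keep <- filter_common_sets(quants, min_sets = min_sets,
                             total_sets = total_sets)
  quants_kept <- quants[quants$protein_id %in% keep, , drop = FALSE]
  fc_table <- compute_patient_fold_changes(quants_kept, design,
                                           average = average)
  fc_passed <- filter_fold_change(fc_table, threshold = fc_threshold)
  trend_passed <- filter_trend(fc_passed, min_agree = min_agree,
                               n_patients = sum(design$role == "patient"))
  list(table = trend_passed,
       waterfall = c(identified = n_identified,
                     common_sets = length(keep),
                     fold_change = nrow(fc_passed),
                     trend = nrow(trend_passed)))
}

#' Express a trend threshold as a population percentage
#'
#' @param min_agree Agreeing patients required.
#' @param n_patients Total patients.
#' @return The rounded percentage of the population, e.g. 7 of 11 -> 64.
#' @examples
#' trend_threshold_percent(7, 11)
#' @export
trend_threshold_percent <- function(min_agree, n_patients) {
  round(100 * min_agree / n_patients)
}
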