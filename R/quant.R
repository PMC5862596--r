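#' Compute PSM-level reporter ratios against the pooled control
#'
#' Each PSM's tumor-channel intensities (115-117) are divided by its
#' pooled-control intensity (channel 114). Rows whose channel-114 intensity
#' is zero, negative or missing cannot be ratioed; they are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param psms Data frame of PSM records with intensity columns `i114`,
#'   `i115`, `i116`, `i117`.
#' @param median_center Logical; if `TRUE`, each ratio column is divided by
#'   its median over all PSMs (global loading normalization). Off by
#'   default.
#' @return The retained PSM rows with added ratio columns `r115`, `r116`,
#'   `r117`; attribute `n_excluded` counts dropped rows.
#' @examples
#' psm <- data.frame(i114 = 100, i115 = 320, i116 = 100, i117 = 50)
#' compute_psm_ratios(psm)[, c("r115", "r116", "r117")]
#' @export
compute_psm_ratios <- function(psms, median_center = FALSE) {
  stopifnot(all(c("i114", "i115", "i116", "i117") %in% names(psms)))
  ok <- !is.na(psms$i114) & psms$i114 > 0
  n_excluded <- sum(!ok)
  out <- psms[ok, , drop = FALSE]
  for (ch in c("i115", "i116", "i117")) {
    out[[sub("i", "r", ch)]] <- out[[ch]] / out$i114
  }
  if (median_center) {
    for (rc in c("r115", "r116", "r117")) {
      m <- stats::median(out[[rc]], na.rm = TRUE)
      if (is.finite(m) && m > 0) out[[rc]] <- out[[rc]] / m
    }
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Aggregate PSM ratios to protein-level fold changes
#'
#' Rolls PSM-level reporter ratios up to one fold change per protein,
#' channel, engine and 4-plex set, and applies the identification rule that
#' a protein must be supported by at least `min_unique` distinct unique
#' peptide sequences (modified forms of one sequence count once). The
#' per-channel protein ratio is the median (default) or mean of its PSM
#' ratios.
#'
#' @param psms PSM data frame (`protein_id`, `peptide_seq`, `is_unique`,
#'   `engine`, `set_id`, `i114`..`i117`); may span several engines and
#'   sets, which are aggregated independently.
#' @param min_unique Minimum distinct unique peptides per protein per set
#'   (default 2).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @param median_center Passed to [compute_psm_ratios()].
#' @return Data frame with one row per retained protein x engine x set:
#'   `protein_id`, `engine`, `set_id`, `n_unique_peptides`, `r115`,
#'   `r116`, `r117`. Attributes: `n_dropped` (protein/set groups failing
#'   the unique-peptide rule), `n_excluded_psms` (zero-denominator rows).
#' @examples
#' psm <- data.frame(protein_id = "P1",
#'                   peptide_seq = c("AAK", "CCK", "DDK"),
#'                   is_unique = TRUE, engine = "engine1", set_id = 1,
#'                   i114 = 100, i115 = c(200, 300, 1000),
#'                   i116 = 100, i117 = 100)
#' aggregate_protein_ratios(psm)$r115  # median of 2, 3, 10
#' @export
aggregate_protein_ratios <- function(psms, min_unique = 2L,
                                     aggregate = c("median", "mean"),
                                     median_center = FALSE) {
  aggregate <- match.arg(aggregate)
  if (nrow(psms) == 0L) {
    warning("no PSM records supplied; returning empty quant table")
    return(empty_quant_table())
  }
  stopifnot(all(c("protein_id", "peptide_seq", "is_unique", "engine",
                  "set_id") %in% names(psms)))
  ratios <- compute_psm_ratios(psms, median_center = median_center)
  n_excluded <- attr(ratios, "n_excluded")
  if (nrow(ratios) == 0L) {
    warning("all PSM records excluded (zero pooled-control intensity)")
    out <- empty_quant_table()
    attr(out, "n_excluded_psms") <- n_excluded
    return(out)
  }
  agg_fun <- if (aggregate == "median") stats::median else mean
  key <- interaction(ratios$engine, ratios$set_id, ratios$protein_id,
                     drop = TRUE)
  groups <- split(ratios, key)
  rows <- lapply(groups, function(g) {
    data.frame(protein_id = g$protein_id[1],
               engine = g$engine[1],
               set_id = g$set_id[1],
               n_unique_peptides = length(unique(g$peptide_seq[g$is_unique])),
               r115 = agg_fun(g$r115),
               r116 = agg_fun(g$r116),
               r117 = agg_fun(g$r117),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$n_unique_peptides >= min_unique
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$engine, out$set_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_excluded_psms") <- n_excluded
  out
}

empty_quant_table <- function() {
  out <- data.frame(protein_id = character(0), engine = character(0),
                    set_id = integer(0), n_unique_peptides = integer(0),
                    r115 = numeric(0), r116 = numeric(0), r117 = numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- 0L
  attr(out, "n_excluded_psms") <- 0L
  out
}
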