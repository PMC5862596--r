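#' Construct a 4-plex labelling design
#'
#' Describes how iTRAQ reporter channels map to sample roles in each 4-plex
#' set. Channel 114 always carries the pooled control (a pool of all patients'
#' matched control tissue); the remaining channels carry individual tumor
#' lysates, except for at most one channel reserved for a pooled tumor sample.
#'
#' The default layout for 11 patients in 4 sets places three patients per set
#' in channels 115/116/117 for sets 1-3, patients 10 and 11 in channels
#' 115/116 of set 4, and the pooled tumor in channel 117 of set 4.
#'
#' @param n_patients Number of tumor/matched-control pairs (default 11).
#' @param n_sets Number of 4-plex sets (default 4).
#' @param pooled_tumor Logical; reserve channel 117 of the last set for a
#'   pooled tumor sample (default `TRUE`).
#' @return A data frame of class `plex_design` with columns `set_id`,
#'   `channel`, `role` (one of `"pooled_control"`, `"patient"`,
#'   `"pooled_tumor"`) and `patient_id` (`NA` for pools).
#' @examples
#' plex_design()
#' @export
plex_design <- function(n_patients = 11L, n_sets = 4L, pooled_tumor = TRUE) {
  n_patients <- as.integer(n_patients)
  n_sets <- as.integer(n_sets)
  if (n_patients < 1L || n_sets < 1L) {
    stop("n_patients and n_sets must be positive", call. = FALSE)
  }
  capacity <- 3L * n_sets - as.integer(pooled_tumor)
  if (n_patients > capacity) {
    stop(sprintf("design error: %d patients do not fit in %d sets (capacity %d)",
                 n_patients, n_sets, capacity), call. = FALSE)
  }
  tumor_channels <- c(115L, 116L, 117L)
  rows <- list()
  patient <- 1L
  for (s in seq_len(n_sets)) {
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = s, channel = 114L, role = "pooled_control",
      patient_id = NA_character_, stringsAsFactors = FALSE)
    for (ch in tumor_channels) {
      if (pooled_tumor && s == n_sets && ch == 117L) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = s, channel = ch, role = "pooled_tumor",
          patient_id = NA_character_, stringsAsFactors = FALSE)
      } else if (patient <= n_patients) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = s, channel = ch, role = "patient",
          patient_id = sprintf("patient_%02d", patient),
          stringsAsFactors = FALSE)
        patient <- patient + 1L
      }
    }
  }
  design <- do.call(rbind, rows)
  validate_plex_design(design)
}

#' Validate a plex design
#'
#' Checks the structural invariants of a [plex_design()] table: channel 114
#' is the pooled control in every set, each patient occupies exactly one
#' set/channel, and at most one channel overall is a pooled tumor.
#'
#' @param design A data frame with columns `set_id`, `channel`, `role`,
#'   `patient_id`.
#' @return The design, classed `plex_design`, invisibly checked.
#' @export
validate_plex_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("set_id", "channel", "role", "patient_id") %in% names(design)))
  if (!all(design$channel %in% c(114L, 115L, 116L, 117L))) {
    stop("design error: channels must be in 114:117", call. = FALSE)
  }
  for (s in unique(design$set_id)) {
    ch114 <- design$role[design$set_id == s & design$channel == 114L]
    if (length(ch114) != 1L || ch114 != "pooled_control") {
      stop(sprintf("design error: set %s channel 114 must be the pooled control", s),
           call. = FALSE)
    }
  }
  pats <- design$patient_id[design$role == "patient"]
  if (anyDuplicated(pats)) {
    stop(sprintf("design error: patient mapped twice: %s",
                 paste(unique(pats[duplicated(pats)]), collapse = ", ")),
         call. = FALSE)
  }
  if (sum(design$role == "pooled_tumor") > 1L) {
    stop("design error: at most one pooled tumor channel allowed", call. = FALSE)
  }
  if (any(design$role == "pooled_control" & design$channel != 114L)) {
    stop("design error: pooled control only in channel 114", call. = FALSE)
  }
  class(design) <- c("plex_design", "data.frame")
  design
}

#' @export
print.plex_design <- function(x, ...) {
  cat(sprintf("4-plex labelling design: %d sets, %d patients%s\n",
              length(unique(x$set_id)), sum(x$role == "patient"),
              if (any(x$role == "pooled_tumor")) ", pooled tumor present" else ""))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# patients handled by a design, in order
design_patients <- function(design) {
  design$patient_id[design$role == "patient"]
}
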