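#' @keywords internal
#' Hash a configuration for output provenance headers
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("proteopanel"))
  h <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# proteopanel %s config=%s", ver, h)
}

#' Write a tabular output with a provenance header
#'
#' All pipeline tables are written as TSV (or CSV) with a leading comment
#' line naming the producing package version and the MD5 hash of the
#' configuration, so any output can be traced to the run that made it.
#'
#' @param x Data frame to write.
#' @param path Output file path.
#' @param config Optional configuration object hashed into the header.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(x, path, config = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular output written by this package
#'
#' Skips provenance comment lines and restores the data frame.
#'
#' @param path File path.
#' @param sep Field separator used at write time.
#' @return Data frame.
#' @export
read_table_prov <- function(path, sep = "\t") {
  utils::read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a PSM reporter-intensity table
#'
#' Expects the TSV schema `protein_id`, `peptide_seq`, `is_unique`,
#' `set_id`, `engine`, `i114`, `i115`, `i116`, `i117`.
#'
#' @param path TSV file path.
#' @return PSM data frame.
#' @export
read_psm_table <- function(path) {
  x <- read_table_prov(path)
  need <- c("protein_id", "peptide_seq", "is_unique", "set_id", "engine",
            "i114", "i115", "i116", "i117")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("PSM table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  x$is_unique <- as.logical(x$is_unique)
  x
}

#' Read a weighted edge list
#'
#' Expects TSV columns `node_a`, `node_b`, `confidence` and returns a
#' [ppi_network()].
#'
#' @param path TSV file path.
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path) {
  ppi_network(edges = read_table_prov(path))
}

#' Write a network's edge list
#'
#' @param net A [ppi_network()].
#' @param path Output TSV path.
#' @param config Optional configuration hashed into the header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, config = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  write_table_prov(net$edges, path, config = config)
}

#' Read an MRM peak-area table
#'
#' Expects the CSV schema `protein_id`, `peptide_seq`, `transition_id`,
#' `sample_id`, `condition`, `patient_id`, `replicate`, `area`.
#'
#' @param path CSV file path.
#' @return Peak-area data frame.
#' @export
read_mrm_areas <- function(path) {
  x <- read_table_prov(path, sep = ",")
  need <- c("transition_id", "sample_id", "condition", "patient_id",
            "replicate", "area")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("MRM area table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Write and re-read a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML so a run can be
#' reproduced from its config file alone.
#'
#' @param config A [pipeline_config()] or [sim_config()].
#' @param path YAML file path.
#' @return For `write_config`, `path` invisibly; for `read_config`, the
#'   restored configuration object.
#' @export
write_config <- function(config, path) {
  kind <- class(config)[1]
  yaml::write_yaml(c(list(.kind = kind), unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- raw$.kind
  raw$.kind <- NULL
  if (identical(kind, "sim_config")) {
    return(do.call(sim_config, raw))
  }
  if (identical(kind, "pipeline_config")) {
    raw$sim <- do.call(sim_config, raw$sim)
    return(do.call(pipeline_config, raw))
  }
  stop(sprintf("unknown config kind in %s", path), call. = FALSE)
}

#' Write every synthetic input table of a study to a directory
#'
#' Materializes the simulator outputs in their on-disk formats: PSM TSVs
#' (one per engine per set), the truth table, the network edge list, the
#' external reference table and the MRM peak-area CSV.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param panel_spec Optional MRM panel specification; default picks the
#'   first three planted proteins (if any) with 3 peptides x 3
#'   transitions.
#' @return Character vector of written file paths, invisibly.
#' @export
write_simulated_study <- function(config, outdir, panel_spec = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config)
  design <- plex_design(config$n_patients, config$n_sets)
  psms <- simulate_psm_tables(truth, design, config)
  net <- simulate_network(config, truth)
  refs <- simulate_external_refs(truth, config)
  paths <- character(0)

  truth_df <- cbind(truth$proteins,
                    as.data.frame(truth$log2fc, optional = TRUE))
  p <- file.path(outdir, "truth.tsv")
  write_table_prov(truth_df, p, config); paths <- c(paths, p)

  for (e in unique(psms$engine)) {
    for (s in unique(psms$set_id)) {
      sub <- psms[psms$engine == e & psms$set_id == s, ]
      p <- file.path(outdir, sprintf("psm_%s_set%d.tsv", e, s))
      write_table_prov(sub, p, config); paths <- c(paths, p)
    }
  }
  p <- file.path(outdir, "network_edges.tsv")
  write_edge_list(net, p, config); paths <- c(paths, p)
  p <- file.path(outdir, "external_refs.tsv")
  write_table_prov(refs, p, config); paths <- c(paths, p)

  if (is.null(panel_spec)) {
    planted <- truth$proteins$protein_id[truth$proteins$direction != "null"]
    if (length(planted) >= 1) {
      panel_spec <- make_panel_spec(utils::head(planted, 3))
    }
  }
  if (!is.null(panel_spec)) {
    areas <- simulate_mrm(truth, panel_spec, config)
    p <- file.path(outdir, "mrm_areas.csv")
    write_table_prov(areas, p, config, sep = ","); paths <- c(paths, p)
    p <- file.path(outdir, "mrm_panel.csv")
    write_table_prov(panel_spec, p, config, sep = ","); paths <- c(paths, p)
  }
  p <- file.path(outdir, "sim_config.yaml")
  write_config(config, p); paths <- c(paths, p)
  invisible(paths)
}
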