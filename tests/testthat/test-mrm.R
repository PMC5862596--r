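area_row <- function(transition_id, sample_id, condition, patient_id,
                     replicate, area, protein_id = "P1",
                     peptide_seq = "pep1") {
  data.frame(protein_id = protein_id, peptide_seq = peptide_seq,
             transition_id = transition_id, sample_id = sample_id,
             condition = condition, patient_id = patient_id,
             replicate = replicate, area = area, stringsAsFactors = FALSE)
}

# balanced two-condition area table from a named list patient -> c(tumor, control)
paired_areas <- function(values, transition_id = "t1", protein_id = "P1",
                         peptide_seq = "pep1") {
  do.call(rbind, lapply(names(values), function(p) {
    rbind(area_row(transition_id, paste0("T", p), "tumor", p, 1,
                   values[[p]][1], protein_id, peptide_seq),
          area_row(transition_id, paste0("C", p), "control", p, 1,
                   values[[p]][2], protein_id, peptide_seq))
  }))
}

test_that("method building enforces panel minimums and uniqueness", {
  expect_equal(build_method(make_panel_spec("P1"))$n_transitions, 9)
  # 46 peptides x 3 transitions gives the full 138-transition method
  spec46 <- rbind(make_panel_spec(sprintf("P%d", 1:8), n_peptides = 5),
                  make_panel_spec("P9", n_peptides = 6))
  m <- build_method(spec46)
  expect_equal(m$n_transitions, 138)
  expect_equal(m$dwell_time, 0.005)
  expect_equal(m$pause_time, 0.003)
  expect_equal(m$transitions$rt_window[1], 1)

  expect_error(build_method(make_panel_spec("P1", n_peptides = 2)),
               "fewer than 3 peptides.*P1")
  expect_error(build_method(make_panel_spec("P1", n_transitions = 2)),
               "fewer than 3 transitions")
  dup <- rbind(make_panel_spec("P1"), make_panel_spec("P1"))
  expect_error(build_method(dup), "duplicate transition")
})

test_that("rollup sums transitions, medians peptides, averages replicates", {
  spec <- make_panel_spec("P1", n_peptides = 3, n_transitions = 3)
  method <- build_method(spec)
  # one peptide with transition areas 100/200/300 in one sample
  t_pep1 <- spec$transition_id[spec$peptide_seq == spec$peptide_seq[1]]
  one_pep <- do.call(rbind, lapply(1:3, function(i)
    area_row(t_pep1[i], "T01", "tumor", "patient_01", 1, i * 100)))
  out <- rollup_protein_abundance(one_pep, method)
  expect_equal(out$log2_abundance, log2(600))
  expect_equal(out$n_transitions_detected, 3L)

  # two peptides at log2 abundances 10 and 12: protein at the median 11
  t_pep2 <- spec$transition_id[spec$peptide_seq == spec$peptide_seq[4]]
  two_pep <- rbind(
    area_row(t_pep1[1], "T01", "tumor", "patient_01", 1, 2^10),
    area_row(t_pep2[1], "T01", "tumor", "patient_01", 1, 2^12))
  expect_equal(rollup_protein_abundance(two_pep, method)$log2_abundance, 11)

  # replicates are averaged, so duplicating every row changes nothing
  dup <- rbind(two_pep, two_pep)
  expect_equal(rollup_protein_abundance(dup, method)$log2_abundance, 11)

  # all-zero areas mean not detected, not zero abundance
  zeros <- area_row(spec$transition_id[1], "T01", "tumor", "patient_01",
                    1:3, 0, "P1", spec$peptide_seq[1])
  expect_warning(none <- rollup_protein_abundance(zeros, method),
                 "no transition")
  expect_equal(nrow(none), 0)

  expect_error(rollup_protein_abundance(
    area_row("bogus", "T01", "tumor", "patient_01", 1, 10), method),
    "unknown transition")
})

test_that("identical tumor and control abundances are never significant", {
  vals <- setNames(lapply(1:5, function(i) c(100, 100)),
                   sprintf("patient_%02d", 1:5))
  spec <- make_panel_spec("P1")
  areas <- paired_areas(vals, spec$transition_id[1], "P1",
                        spec$peptide_seq[1])
  res <- test_dysregulation(rollup_protein_abundance(areas, build_method(spec)))
  expect_equal(res$log2fc, 0)
  expect_false(res$significant)
  expect_true(res$tested)
})

test_that("proteins with too few complete pairs are reported untested", {
  vals <- setNames(lapply(1:2, function(i) c(300, 100)),
                   sprintf("patient_%02d", 1:2))
  spec <- make_panel_spec("P1")
  areas <- paired_areas(vals, spec$transition_id[1], "P1",
                        spec$peptide_seq[1])
  res <- test_dysregulation(rollup_protein_abundance(areas, build_method(spec)))
  expect_false(res$tested)
  expect_false(res$significant)
  expect_true(is.na(res$p_value))
})

test_that("label swap negates fold changes and preserves p-values", {
  cfg <- sim_config(n_proteins = 3, frac_up = 1, frac_down = 0, seed = 41)
  truth <- simulate_truth(cfg)
  spec <- make_panel_spec(truth$proteins$protein_id)
  areas <- simulate_mrm(truth, spec, cfg)
  method <- build_method(spec)
  res <- test_dysregulation(rollup_protein_abundance(areas, method))
  swapped <- areas
  swapped$condition <- ifelse(areas$condition == "tumor", "control", "tumor")
  res_sw <- test_dysregulation(rollup_protein_abundance(swapped, method))
  expect_equal(res_sw$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
})

test_that("a planted 1.7 log2 effect is recovered within 0.3 log2 units", {
  lfc <- matrix(1.7, 1, 11,
                dimnames = list("P1", sprintf("patient_%02d", 1:11)))
  truth <- ground_truth(data.frame(protein_id = "P1", direction = "up",
                                   stringsAsFactors = FALSE), lfc)
  cfg <- sim_config(n_proteins = 1, noise_cv = 0.2, seed = 43)
  spec <- make_panel_spec("P1")
  areas <- simulate_mrm(truth, spec, cfg)
  res <- test_dysregulation(rollup_protein_abundance(areas, build_method(spec)))
  expect_lt(abs(res$log2fc - 1.7), 0.3)
  expect_true(res$significant)
  expect_equal(res$n_pairs, 10L)
})

test_that("a panel-sized planted effect lands in the published range", {
  # S100A9-like protein: true fold change 3.2, ten pairs, CV 20%
  lfc <- matrix(log2(3.2), 1, 11,
                dimnames = list("S100A9", sprintf("patient_%02d", 1:11)))
  truth <- ground_truth(data.frame(protein_id = "S100A9", direction = "up",
                                   stringsAsFactors = FALSE), lfc)
  cfg <- sim_config(n_proteins = 1, noise_cv = 0.2, seed = 44)
  spec <- make_panel_spec("S100A9")
  areas <- simulate_mrm(truth, spec, cfg)
  res <- test_dysregulation(rollup_protein_abundance(areas, build_method(spec)))
  expect_gt(2^res$log2fc, 2.3)
  expect_lt(2^res$log2fc, 4.4)
  expect_true(res$significant)
})
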