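test_that("sim_config validates its invariants", {
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5), "frac_up")
  expect_error(sim_config(noise_cv = 0), "noise_cv")
  expect_error(sim_config(trend_consistency = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(mrm_n_pairs = 12, n_patients = 11), "mrm_n_pairs")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("plex_design places pools correctly and rejects bad designs", {
  d <- plex_design()
  expect_equal(sum(d$role == "pooled_control"), 4)
  expect_true(all(d$channel[d$role == "pooled_control"] == 114))
  expect_equal(sum(d$role == "patient"), 11)
  expect_equal(d$channel[d$role == "pooled_tumor"], 117)
  expect_equal(d$set_id[d$role == "pooled_tumor"], 4)
  expect_error(plex_design(n_patients = 20, n_sets = 4), "do not fit")
  bad <- d
  bad$patient_id[bad$set_id == 2 & bad$channel == 115] <- "patient_01"
  expect_error(validate_plex_design(bad), "mapped twice")
})

test_that("truth generation plants the requested effect structure", {
  cfg <- sim_config(n_proteins = 100, frac_up = 0.2, frac_down = 0.1, seed = 1)
  truth <- simulate_truth(cfg)
  expect_equal(sum(truth$proteins$direction == "up"), 20)
  expect_equal(sum(truth$proteins$direction == "down"), 10)
  null_ids <- truth$proteins$direction == "null"
  expect_true(all(truth$log2fc[null_ids, ] == 0))

  # no planted effects -> every protein null
  t0 <- simulate_truth(sim_config(n_proteins = 50, frac_up = 0,
                                  frac_down = 0, seed = 2))
  expect_true(all(t0$proteins$direction == "null"))
  expect_true(all(t0$log2fc == 0))

  # perfect trend consistency -> all per-patient FCs above 1 for up proteins
  t1 <- simulate_truth(sim_config(n_proteins = 50, frac_up = 0.5,
                                  frac_down = 0, trend_consistency = 1,
                                  seed = 3))
  up <- t1$proteins$direction == "up"
  expect_true(all(2^t1$log2fc[up, ] > 1))
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 30, n_hubs = 1, seed = 11)
  expect_identical(simulate_truth(cfg), simulate_truth(cfg))
  truth <- simulate_truth(cfg)
  design <- plex_design()
  expect_identical(simulate_psm_tables(truth, design, cfg),
                   simulate_psm_tables(truth, design, cfg))
  expect_identical(simulate_network(cfg, truth), simulate_network(cfg, truth))
  expect_identical(simulate_external_refs(truth, cfg),
                   simulate_external_refs(truth, cfg))
  spec <- make_panel_spec("P0001")
  expect_identical(simulate_mrm(truth, spec, cfg),
                   simulate_mrm(truth, spec, cfg))
})

test_that("written study files are byte-identical across runs", {
  cfg <- sim_config(n_proteins = 15, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulated_study(cfg, d1)
  p2 <- write_simulated_study(cfg, d2)
  expect_equal(basename(p1), basename(p2))
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
})

test_that("PSM tables follow the pooled-reference intensity model", {
  # null protein with near-zero noise: all channel ratios ~ 1
  cfg <- sim_config(n_proteins = 10, frac_up = 0, frac_down = 0,
                    noise_cv = 1e-6, seed = 7)
  truth <- simulate_truth(cfg)
  psms <- simulate_psm_tables(truth, plex_design(), cfg)
  r <- compute_psm_ratios(psms)
  expect_true(all(abs(c(r$r115, r$r116, r$r117) - 1) < 1e-4))

  # engine detection flags respected
  cfg2 <- sim_config(n_proteins = 5, seed = 8)
  truth2 <- simulate_truth(cfg2)
  truth2$proteins$in_engine1 <- TRUE
  truth2$proteins$in_engine2 <- FALSE
  psms2 <- simulate_psm_tables(truth2, plex_design(), cfg2)
  expect_true(all(psms2$engine == "engine1"))
})

test_that("planted fold change is recovered by the median PSM ratio", {
  # uniform log2fc of 1 for every patient, ~50 PSMs, CV 5%:
  # the median ratio in a patient channel must land close to 2
  cfg <- sim_config(n_proteins = 1, frac_up = 0, frac_down = 0,
                    noise_cv = 0.05, peptides_per_protein_mean = 10,
                    psms_per_peptide_mean = 5, seed = 9)
  lfc <- matrix(1, 1, 11, dimnames = list("P0001", sprintf("patient_%02d", 1:11)))
  truth <- ground_truth(data.frame(protein_id = "P0001", direction = "up",
                                   stringsAsFactors = FALSE), lfc)
  psms <- simulate_psm_tables(truth, plex_design(), cfg)
  sub <- psms[psms$engine == "engine1" & psms$set_id == 1, ]
  expect_gt(nrow(sub), 30)
  med <- median(sub$i115 / sub$i114)  # channel 115 of set 1 = patient_01
  expect_gt(med, 1.9)
  expect_lt(med, 2.1)
})

test_that("simulated networks are connected, weighted and hub-planted", {
  cfg <- sim_config(n_proteins = 100, frac_up = 0.2, frac_down = 0.2,
                    network_nodes = 150, n_hubs = 1,
                    hub_prior_fraction = 0.75, seed = 13)
  truth <- simulate_truth(cfg)
  net <- simulate_network(cfg, truth)
  expect_s3_class(net, "ppi_network")
  expect_true(all(net$edges$confidence > 0 & net$edges$confidence <= 1))
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  expect_true(igraph::is_connected(g))
  # hub wired to 30 of the 40 differential proteins
  hub <- attr(net, "hubs")
  expect_length(hub, 1)
  de <- truth$proteins$protein_id[truth$proteins$direction != "null"]
  expect_equal(common_prior_count(net, hub, de), 30)

  # one edge per incoming node on 3 nodes gives a connected tree
  cfg3 <- sim_config(n_proteins = 3, network_nodes = 3,
                     network_edges_per_node = 1, seed = 14)
  net3 <- simulate_network(cfg3, simulate_truth(cfg3))
  expect_equal(nrow(net3$edges), 2)
  expect_error(ppi_network(edges = data.frame(node_a = "a", node_b = "a",
                                              confidence = 1)), "self-loops")
})

test_that("MRM simulation matches the scheduled panel geometry", {
  cfg <- sim_config(n_proteins = 9, frac_up = 0, frac_down = 0, seed = 15)
  truth <- simulate_truth(cfg)
  # 46 peptides x 3 transitions: 8 proteins with 5 peptides, one with 6
  ids <- truth$proteins$protein_id
  spec <- do.call(rbind, c(
    lapply(ids[1:8], make_panel_spec, n_peptides = 5),
    list(make_panel_spec(ids[9], n_peptides = 6))))
  areas <- simulate_mrm(truth, spec, cfg)
  one_run <- areas[areas$sample_id == "T01" & areas$replicate == 1, ]
  expect_equal(nrow(one_run), 138)
  expect_equal(length(unique(areas$patient_id)), 10)
  expect_equal(sort(unique(areas$replicate)), 1:3)

  # null protein at near-zero noise: tumor/control ratio ~ 1 per transition
  cfg0 <- sim_config(n_proteins = 1, frac_up = 0, frac_down = 0,
                     noise_cv = 1e-6, seed = 16)
  truth0 <- simulate_truth(cfg0)
  a0 <- simulate_mrm(truth0, make_panel_spec("P0001"), cfg0)
  tum <- a0[a0$condition == "tumor" & a0$replicate == 1, ]
  ctl <- a0[a0$condition == "control" & a0$replicate == 1, ]
  key <- function(x) paste(x$transition_id, x$patient_id)
  ratio <- tum$area / ctl$area[match(key(tum), key(ctl))]
  expect_true(all(abs(ratio - 1) < 1e-4))

  expect_error(simulate_mrm(truth0, make_panel_spec("ABSENT"), cfg0),
               "specification error")
})

test_that("external reference tables are complete and normalized", {
  cfg <- sim_config(n_proteins = 40, seed = 17)
  truth <- simulate_truth(cfg)
  refs <- simulate_external_refs(truth, cfg)
  expect_equal(nrow(refs), 40)
  sums <- refs$hpa_high + refs$hpa_medium + refs$hpa_low + refs$hpa_not_detected
  expect_equal(sums, rep(1, 40), tolerance = 1e-12)
  expect_true(all(refs$cptac_fc > 0))
})
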