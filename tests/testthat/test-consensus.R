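quant_row <- function(protein_id, set_id, r115 = 1, r116 = 1, r117 = 1,
                      engine = "engine1") {
  data.frame(protein_id = protein_id, engine = engine, set_id = set_id,
             n_unique_peptides = 2L, r115 = r115, r116 = r116, r117 = r117,
             stringsAsFactors = FALSE)
}

test_that("multi-set detection filter keeps the 3-of-4 boundary", {
  q <- rbind(quant_row("A", 1), quant_row("A", 2), quant_row("A", 3),
             quant_row("B", 1), quant_row("B", 4))
  expect_equal(filter_common_sets(q), "A")
  expect_error(filter_common_sets(q, min_sets = 5), "configuration error")
  expect_error(filter_common_sets(rbind(q, quant_row("C", 1, engine = "engine2"))),
               "single engine")
})

test_that("patient fold changes resolve channels through the design", {
  design <- plex_design()
  # protein seen in all four sets with every tumor channel at 2.0
  q <- do.call(rbind, lapply(1:4, function(s)
    quant_row("A", s, r115 = 2, r116 = 2, r117 = 2)))
  tab <- compute_patient_fold_changes(q, design)
  expect_equal(tab$avg_fc, 2)
  expect_equal(tab$n_sets_detected, 4L)
  # set-4 channel 117 is the pooled tumor: QC column, not a patient
  expect_equal(tab$pooled_tumor_fc, 2)
  fc_cols <- grep("^fc_", names(tab), value = TRUE)
  expect_length(fc_cols, 11)
  expect_true(all(tab[, fc_cols] == 2))

  # geometric mean symmetry: 2.0 and 0.5 average to 1
  q2 <- rbind(quant_row("B", 1, r115 = 2, r116 = 0.5, r117 = 1))
  tab2 <- compute_patient_fold_changes(q2, design)
  expect_equal(tab2$avg_fc, (2 * 0.5 * 1)^(1 / 3))
  expect_equal(compute_patient_fold_changes(q2, design,
                                            average = "arithmetic")$avg_fc,
               mean(c(2, 0.5, 1)))
})

test_that("a uniformly halved protein averages to 0.5", {
  # Decorin-like profile: every patient at 0.5 with zero noise
  design <- plex_design()
  q <- do.call(rbind, lapply(1:4, function(s)
    quant_row("DCN", s, r115 = 0.5, r116 = 0.5, r117 = 0.5)))
  tab <- compute_patient_fold_changes(q, design)
  expect_equal(tab$avg_fc, 0.5)
  flt <- filter_fold_change(tab)
  expect_equal(flt$direction, "down")
})

test_that("fold-change filter applies inclusive reciprocal thresholds", {
  tab <- data.frame(protein_id = c("A", "B", "C", "D"),
                    avg_fc = c(1.5, 0.6, 1.43, 1 / 1.5),
                    fc_patient_01 = 1)
  out <- filter_fold_change(tab)
  expect_equal(out$protein_id, c("A", "B", "D"))
  expect_equal(out$direction, c("up", "down", "down"))
  expect_error(filter_fold_change(tab, threshold = 1), "configuration error")
})

test_that("trend filter counts agreeing patients with FC=1 as disagreement", {
  mk <- function(id, fcs, direction) {
    out <- data.frame(protein_id = id, avg_fc = exp(mean(log(fcs))),
                      direction = direction)
    for (i in seq_along(fcs)) out[[sprintf("fc_patient_%02d", i)]] <- fcs[i]
    out
  }
  keep <- filter_trend(mk("A", c(rep(2, 7), rep(0.5, 4)), "up"))
  expect_equal(keep$protein_id, "A")
  expect_equal(keep$n_trend_agree, 7)
  drop <- filter_trend(mk("B", c(rep(2, 6), rep(0.9, 5)), "up"))
  expect_equal(nrow(drop), 0)
  exact_one <- filter_trend(mk("C", c(rep(2, 6), 1, rep(0.5, 4)), "up"))
  expect_equal(nrow(exact_one), 0)
  expect_error(filter_trend(mk("A", rep(2, 11), "up"), min_agree = 12),
               "configuration error")
})

test_that("engine intersection keeps agreed directions and logs conflicts", {
  l1 <- data.frame(protein_id = c("A", "B"), direction = c("up", "down"))
  l2 <- data.frame(protein_id = c("A", "C"), direction = c("up", "up"))
  out <- intersect_engines(l1, l2)
  expect_equal(out$protein_id, "A")
  expect_equal(attr(out, "n_conflicts"), 0L)

  l3 <- data.frame(protein_id = "A", direction = "up")
  l4 <- data.frame(protein_id = "A", direction = "down")
  expect_message(conf <- intersect_engines(l3, l4), "conflict")
  expect_equal(nrow(conf), 0)
  expect_equal(attr(conf, "conflicts"), "A")
})

test_that("union combines engines and excludes conflicted proteins", {
  l1 <- data.frame(protein_id = c("A", "B"), direction = c("up", "up"))
  l2 <- data.frame(protein_id = c("C", "D", "E"), direction = "down")
  expect_equal(nrow(combine_union(l1, l2)), 5)
  expect_equal(combine_union(l1, l1)$protein_id, l1$protein_id)

  # cardinality identity |union| = |l1| + |l2| - |intersection| - 2*conflicts
  l3 <- data.frame(protein_id = c("A", "B", "C"),
                   direction = c("up", "up", "down"))
  l4 <- data.frame(protein_id = c("A", "B", "D"),
                   direction = c("down", "up", "up"))
  inter <- suppressMessages(intersect_engines(l3, l4))
  uni <- suppressMessages(combine_union(l3, l4))
  expect_equal(nrow(uni),
               nrow(l3) + nrow(l4) - nrow(inter) - 2 * attr(uni, "n_conflicts"))
  expect_equal(uni$protein_id, c("B", "C", "D"))
})

test_that("external concordance applies the sign and 50% rules", {
  cons <- data.frame(protein_id = c("A", "B", "C", "D"),
                     direction = c("up", "down", "up", "up"))
  refs <- data.frame(protein_id = c("A", "B", "C"),
                     cptac_fc = c(7.9, NA, NA),
                     hpa_high = c(NA, 0.6, 0.25),
                     hpa_medium = c(NA, 0, 0.25))
  out <- concordance_external(cons, refs)
  expect_true(out$cptac_concordant[1])          # up vs reference FC 7.9
  expect_false(out$hpa_concordant[2])           # down vs high 0.6
  expect_true(out$hpa_concordant[3])            # inclusive 50% boundary
  expect_true(out$no_reference[4])
  expect_equal(attr(out, "n_concordant_all"), 2)
})

test_that("each consensus stage matches a brute-force recount", {
  design <- plex_design()
  for (seed in 1:20) {
    q <- random_quant_fixture(seed, n_proteins = 200)
    keep <- filter_common_sets(q)
    expect_identical(keep, oracle_common_sets(q, 3))

    qk <- q[q$protein_id %in% keep, ]
    tab <- compute_patient_fold_changes(qk, design)
    fcp <- filter_fold_change(tab)
    trd <- filter_trend(fcp)
    oracle <- oracle_fc_chain(qk, design, 1.5, 7)

    o_avg <- vapply(oracle, `[[`, numeric(1), "avg_fc")[tab$protein_id]
    expect_equal(tab$avg_fc, unname(o_avg))
    o_pass_fc <- names(Filter(function(x) !is.na(x$direction), oracle))
    expect_identical(fcp$protein_id, sort(o_pass_fc))
    o_pass_tr <- names(Filter(function(x) isTRUE(x$trend_ok), oracle))
    expect_identical(trd$protein_id, sort(o_pass_tr))
  }
})

test_that("the filter chain output shrinks monotonically", {
  cfg <- sim_config(n_proteins = 80, seed = 31)
  truth <- simulate_truth(cfg)
  design <- plex_design()
  q <- aggregate_protein_ratios(simulate_psm_tables(truth, design, cfg))
  for (e in c("engine1", "engine2")) {
    res <- consensus_filter(q[q$engine == e, ], design)
    expect_true(all(diff(res$waterfall) <= 0))
  }
})

test_that("trend threshold of 7 in 11 patients is 64% of the population", {
  expect_identical(trend_threshold_percent(7, 11), 64)
})
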