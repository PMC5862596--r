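# Brute-force oracles and small fixture builders shared across tests.
# Oracles use plain loops and dense algebra, independent of the package's
# vectorized / sparse implementations.

# naive recount: proteins present in >= min_sets distinct sets
oracle_common_sets <- function(quants, min_sets) {
  keep <- character(0)
  for (id in unique(quants$protein_id)) {
    n <- length(unique(quants$set_id[quants$protein_id == id]))
    if (n >= min_sets) keep <- c(keep, id)
  }
  sort(keep)
}

# naive per-protein geometric-mean fold change and filter decisions
oracle_fc_chain <- function(quants, design, threshold, min_agree) {
  pats <- design$patient_id[design$role == "patient"]
  res <- list()
  for (id in unique(quants$protein_id)) {
    sub <- quants[quants$protein_id == id, ]
    fc <- rep(NA_real_, length(pats))
    names(fc) <- pats
    for (r in seq_len(nrow(sub))) {
      for (ch in c(115L, 116L, 117L)) {
        hit <- design[design$set_id == sub$set_id[r] &
                        design$channel == ch & design$role == "patient", ]
        if (nrow(hit) == 1L) fc[hit$patient_id] <- sub[[paste0("r", ch)]][r]
      }
    }
    avail <- fc[!is.na(fc)]
    avg <- exp(mean(log(avail)))
    dir <- if (avg >= threshold) "up" else if (avg <= 1 / threshold) "down" else NA
    trend_ok <- FALSE
    if (!is.na(dir)) {
      agree <- if (dir == "up") sum(avail > 1) else sum(avail < 1)
      trend_ok <- agree >= min_agree
    }
    res[[id]] <- list(avg_fc = avg, direction = dir, trend_ok = trend_ok)
  }
  res
}

# randomized single-engine quant fixture (independent of the simulator)
random_quant_fixture <- function(seed, n_proteins = 200, n_sets = 4) {
  set.seed(seed)
  n_in <- sample(n_sets, n_proteins, replace = TRUE)
  rows <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    sets <- sort(sample(seq_len(n_sets), n_in[i]))
    rows[[i]] <- data.frame(
      protein_id = sprintf("Q%03d", i), engine = "engine1", set_id = sets,
      n_unique_peptides = 2L,
      r115 = stats::rlnorm(n_in[i], 0, 0.7),
      r116 = stats::rlnorm(n_in[i], 0, 0.7),
      r117 = stats::rlnorm(n_in[i], 0, 0.7),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# dense closed-form propagation: (1 - alpha) (I - alpha W')^{-1} Y
oracle_propagation <- function(net, priors, alpha) {
  nodes <- sort(net$nodes)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[r]; b <- net$edges$node_b[r]
    W[a, b] <- W[a, b] + net$edges$confidence[r]
    W[b, a] <- W[b, a] + net$edges$confidence[r]
  }
  d <- rowSums(W)
  Wn <- diag(1 / sqrt(d)) %*% W %*% diag(1 / sqrt(d))
  y <- as.numeric(nodes %in% priors)
  f <- (1 - alpha) * solve(diag(n) - alpha * Wn, y)
  stats::setNames(as.numeric(f), nodes)
}

# small random connected weighted graph (preferential attachment backbone)
random_test_network <- function(seed, n_nodes, m = 2) {
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  ppi_network(nodes, data.frame(node_a = nodes[el[, 1]],
                                node_b = nodes[el[, 2]],
                                confidence = stats::runif(nrow(el), 0.5, 1),
                                stringsAsFactors = FALSE))
}

# the validated nine-protein panel with its published tumor/normal fold
# changes (ratio scale), used to plant panel-sized effects
validated_panel_fcs <- c(S100A9 = 3.2, S100A8 = 3.2, S100A11 = 2.1,
                         LDHA = 1.9, HDGF = 1.8, PKM = 1.7,
                         LUM = 0.6, EHD2 = 0.5, AOC3 = 0.5)

# ground truth with uniform per-patient effects for given ratio-scale FCs,
# plus n_null null proteins
panel_truth <- function(fcs, n_null = 20, n_patients = 11) {
  ids <- c(names(fcs), sprintf("NULL%02d", seq_len(n_null)))
  lfc <- matrix(0, length(ids), n_patients,
                dimnames = list(ids, sprintf("patient_%02d", seq_len(n_patients))))
  lfc[seq_along(fcs), ] <- log2(fcs)
  proteins <- data.frame(
    protein_id = ids,
    direction = c(ifelse(fcs > 1, "up", "down"), rep("null", n_null)),
    panel_member = c(rep(TRUE, length(fcs)), rep(FALSE, n_null)),
    stringsAsFactors = FALSE)
  ground_truth(proteins, lfc)
}
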