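test_that("within-cell standardization removes group location and scale", {
  tab <- simulate_clustered_cohort(40, separation = 1, seed = 3)
  traits <- c("consumption", "escalation_total", "break_point")
  # plant big cell offsets
  tab$consumption[tab$site == "site2"] <- tab$consumption[tab$site == "site2"] + 100
  Z <- standardize_within_group(tab, traits)
  cell <- interaction(tab$sex, tab$site)
  for (g in levels(cell)) {
    expect_lt(abs(mean(Z[cell == g, "consumption"])), 1e-10)
    expect_equal(sd(Z[cell == g, "consumption"]), 1, tolerance = 1e-10)
  }
  # invariance to per-cell affine transforms
  tab2 <- tab
  for (g in levels(cell))
    tab2$escalation_total[cell == g] <- 3 * tab2$escalation_total[cell == g] + 7
  Z2 <- standardize_within_group(tab2, traits)
  expect_equal(Z[, "escalation_total"], Z2[, "escalation_total"], tolerance = 1e-10)
  # missing propagates, constant trait warns
  tab3 <- tab; tab3$break_point[5] <- NA
  Z3 <- standardize_within_group(tab3, traits)
  expect_true(is.na(Z3[5, "break_point"]))
  tab4 <- tab; tab4$break_point <- 1
  w <- capture_warnings(standardize_within_group(tab4, traits))
  expect_true(all(grepl("constant", w)))
  expect_gte(length(w), 1)
})

test_that("similarity network has the requested density and block structure", {
  tab <- simulate_clustered_cohort(40, separation = 3, seed = 7)
  traits <- setdiff(names(tab), c("id", "site", "sex", "true_cluster"))
  Z <- standardize_within_group(tab, traits)
  net <- build_similarity_network(Z, edge_quantile = 0.8)
  n <- nrow(net$adjacency)
  expect_true(isSymmetric(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))
  density <- sum(net$adjacency) / (n * (n - 1))
  expect_lt(abs(density - 0.20), 0.02)
  # planted groups: within-group edges denser than between
  same <- outer(tab$true_cluster, tab$true_cluster, "==")
  diag(same) <- NA
  expect_gt(mean(net$adjacency[same & !is.na(same)]),
            3 * mean(net$adjacency[!same & !is.na(same)]))
  # three identical individuals form a closed triangle
  Zi <- matrix(rep(c(1, -1, 2, 0.5), each = 6), 6, 4)
  Zi[4:6, ] <- Zi[4:6, ] + matrix(rnorm(12, sd = 3), 3, 4)
  rownames(Zi) <- paste0("r", 1:6)
  net2 <- build_similarity_network(Zi, edge_quantile = 0.5)
  expect_true(all(net2$adjacency[1:3, 1:3][upper.tri(diag(3))] == 1))
})

test_that("the SBM recovers planted blocks and separates clean cliques", {
  g <- sbm_graph(60, p_in = 0.3, p_out = 0.05, seed = 5)
  fit <- fit_sbm(g$network, K = 3, n_sweeps = 150, burn_in = 50, seed = 2)
  expect_gte(adjusted_rand(fit$assignment, g$labels), 0.9)
  expect_true(all(is.finite(fit$log_posterior)))
  # block-diagonal cliques: exact recovery
  A <- matrix(0L, 30, 30)
  for (b in 0:2) A[b * 10 + 1:10, b * 10 + 1:10] <- 1L
  diag(A) <- 0L
  net <- structure(list(ids = sprintf("n%02d", 1:30), adjacency = A,
                        record = list()), class = "similarity_network")
  fitc <- fit_sbm(net, K = 3, n_sweeps = 120, burn_in = 40, seed = 3)
  expect_equal(adjusted_rand(fitc$assignment, rep(1:3, each = 10)), 1)
  expect_gt(mean(diag(fitc$edge_prob)), 0.9)
  # an unstructured graph carries no information about arbitrary labels
  set.seed(11)
  n <- 90
  Ae <- matrix(rbinom(n * n, 1, 0.15), n, n)
  Ae[lower.tri(Ae, diag = TRUE)] <- 0
  Ae <- Ae + t(Ae)
  nete <- structure(list(ids = sprintf("e%02d", 1:n), adjacency = Ae,
                         record = list()), class = "similarity_network")
  fite <- fit_sbm(nete, K = 3, n_sweeps = 100, burn_in = 40, seed = 4)
  expect_lt(abs(adjusted_rand(fite$assignment, rep(1:3, each = 30))), 0.12)
})

test_that("severity labeling tracks the planted gradient and is stable to
           block relabeling", {
  tab <- simulate_clustered_cohort(50, separation = 3, seed = 13)
  traits <- setdiff(names(tab), c("id", "site", "sex", "true_cluster"))
  Z <- standardize_within_group(tab, traits)
  net <- build_similarity_network(Z)
  fit <- fit_sbm(net, K = 3, n_sweeps = 150, burn_in = 50, seed = 5)
  fit <- label_clusters(fit, tab, traits)
  expect_gte(adjusted_rand(fit$labels, tab$true_cluster), 0.9)
  agree <- mean(fit$labels == tab$true_cluster)
  expect_gt(agree, 0.9)   # labels, not just partition, match the construction
  # permuting internal block ids leaves the labeling unchanged
  perm <- c(3L, 1L, 2L)
  fit2 <- fit
  fit2$assignment <- perm[fit$assignment]
  fit2 <- label_clusters(fit2, tab, traits)
  expect_identical(fit2$labels, fit$labels)
  # constant severity traits exercise the tie path
  tab3 <- tab
  for (t in traits) tab3[[t]] <- 1
  expect_warning(label_clusters(fit, tab3, traits), "tie")
})

test_that("cluster contrasts partition the cohort exactly", {
  tab <- simulate_clustered_cohort(30, separation = 3, seed = 17)
  traits <- setdiff(names(tab), c("id", "site", "sex", "true_cluster"))
  Z <- standardize_within_group(tab, traits)
  fit <- fit_sbm(build_similarity_network(Z), K = 3, n_sweeps = 120,
                 burn_in = 40, seed = 6)
  fit <- label_clusters(fit, tab, traits)
  con <- cluster_contrasts(fit)
  sums <- con$vulnerable_vs_rest + con$intermediate_vs_rest +
    con$resilient_vs_rest
  expect_true(all(sums == 1))
  expect_equal(sum(con$vulnerable_vs_rest), sum(fit$labels == "vulnerable"))
})

test_that("allele-by-cluster chi-square matches the closed form", {
  # construct dosages yielding the 2x2 table [[30,10],[10,30]]
  g <- c(rep(0, 40), rep(1, 30), rep(2, 10))
  cl <- c(rep(0, 30), rep(1, 10), rep(0, 8), rep(1, 22), rep(0, 2), rep(1, 8))
  res <- allele_by_cluster_test(g, cl)
  expect_equal(unname(res$table["major_hom", "0"]), 30)
  expect_equal(unname(res$table["carrier", "1"]), 30)
  expect_equal(res$chi2, 20, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # independence table: chi2 = 0
  g2 <- rep(c(0, 1), each = 40)
  cl2 <- rep(c(0, 1, 0, 1), each = 20)
  res2 <- allele_by_cluster_test(g2, cl2)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
  # swapping rows/columns leaves chi2 unchanged
  res3 <- allele_by_cluster_test(2 - g, 1 - cl)
  expect_equal(res3$chi2, res$chi2, tolerance = 1e-10)
  # full-genotype grouping gives df = 2
  res4 <- allele_by_cluster_test(g, cl, grouping = "genotype")
  expect_equal(res4$df, 2)
})
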