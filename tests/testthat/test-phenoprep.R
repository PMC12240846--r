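test_that("inverse-normal transform follows the Blom closed form", {
  out <- quantile_normalize(c(3.2, -1, 7))
  expect_equal(out, c(0, -0.8694238, 0.8694238), tolerance = 1e-6)
  # rank invariance under strictly monotone transforms
  x <- c(0.3, 12, -4, 5.5, 2)
  expect_equal(quantile_normalize(x), quantile_normalize(exp(x)))
  # average-rank convention for ties: two tied minima among n = 4
  out4 <- quantile_normalize(c(1, 1, 5, 9))
  expect_equal(out4[1], out4[2])
  expect_equal(out4[1], qnorm((1.5 - 3 / 8) / 4.25), tolerance = 1e-12)
  # missing preserved; all-tied maps to zero
  expect_equal(quantile_normalize(c(2, NA, 4))[2], NA_real_)
  expect_equal(quantile_normalize(c(3, 3, 3)), c(0, 0, 0))
})

test_that("covariate variance explained matches the analytic decomposition", {
  set.seed(4)
  x <- rnorm(1000)
  expect_equal(suppressWarnings(covariate_variance_explained(x, x)), 1)
  expect_lt(covariate_variance_explained(x, rnorm(1000)), 0.01)
  # trait = covariate + noise with variance ratio 1:3 -> R2 ~ 0.25
  y <- x + rnorm(1000, sd = sqrt(3))
  expect_lt(abs(covariate_variance_explained(y, x) - 0.25), 0.05)
  expect_equal(covariate_variance_explained(x, rep(1, 1000)), 0)
  # categorical covariate with a real group effect
  g <- sample(c("a", "b"), 1000, replace = TRUE)
  y2 <- ifelse(g == "a", 0, 2) + rnorm(1000)
  expect_gt(covariate_variance_explained(y2, g), 0.2)
})

test_that("prepare_trait removes site structure and equalizes variances", {
  cc <- make_cohort(seed = 31, n = 400, n_chrom = 2, h2_poly = 0.2,
                    site_shift = c(site1 = 0, site2 = 10),
                    site_scale = c(site1 = 1, site2 = 3),
                    sex_effect = 1.5)
  tab <- cc$table
  y <- prepare_trait(tab, "trait", c("sex", "batch"))
  sm <- tapply(y, tab$site, mean)
  expect_lt(abs(sm[1] - sm[2]), 0.05)
  sv <- tapply(y, tab$site, var)
  expect_lt(abs(sv[1] - sv[2]), 0.1)
  # the pooled vector is a fixed point of the transform (cross-site ties
  # share average-rank values, so re-applying it changes nothing)
  expect_equal(quantile_normalize(y), y, ignore_attr = TRUE,
               tolerance = 1e-10)
  # sex explained > 2% at these settings and was regressed out per site
  prov <- attr(y, "provenance")
  expect_true(all(vapply(prov$sites, function(s) "sex" %in% s$covariates,
                         TRUE)))
  expect_lt(abs(mean(y[tab$sex == "M"]) - mean(y[tab$sex == "F"])), 0.15)
})

test_that("prepare_trait is invariant to within-site affine transforms", {
  cc <- make_cohort(seed = 33, n = 200, n_chrom = 1)
  tab <- cc$table
  y1 <- prepare_trait(tab, "trait", "sex")
  tab2 <- tab
  s2 <- tab2$site == "site2"
  tab2$trait[s2] <- 5 * tab2$trait[s2] + 100
  tab2$trait[!s2] <- -2 * tab2$trait[!s2] + 7   # negative scale flips ranks
  y2 <- prepare_trait(tab2, "trait", "sex")
  expect_equal(abs(cor(y1[s2], y2[s2], method = "spearman")), 1,
               tolerance = 1e-10)
  # positive affine transform only: full invariance
  tab3 <- tab
  tab3$trait[s2] <- 5 * tab3$trait[s2] + 100
  y3 <- prepare_trait(tab3, "trait", "sex")
  expect_equal(y1, y3, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("missing trait values stay missing and sites can drop out", {
  cc <- make_cohort(seed = 35, n = 60, n_chrom = 1)
  tab <- cc$table
  tab$trait[c(3, 10)] <- NA
  y <- prepare_trait(tab, "trait")
  expect_true(all(is.na(y[c(3, 10)])))
  expect_equal(sum(is.na(y)), 2)
  tab$trait[tab$site == "site2"] <- NA
  y2 <- suppressWarnings(prepare_trait(tab, "trait"))
  expect_true(all(is.na(y2[tab$site == "site2"])))
  prov <- attr(y2, "provenance")
  expect_match(prov$sites$site2$note, "missing")
})

test_that("Spearman correlation matrix applies Bonferroni over distinct pairs", {
  set.seed(8)
  traits <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  traits$V2 <- -traits$V1 + rnorm(200, sd = 1e-8)    # near-perfect anti-rank
  cm <- correlation_matrix(traits)
  expect_equal(cm$m, 45)
  expect_equal(diag(cm$rho), rep(1, 10), ignore_attr = TRUE)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$rho["V1", "V2"], -1, tolerance = 1e-6)
  off <- cm$p[upper.tri(cm$p)]
  expect_equal(cm$p_adj[upper.tri(cm$p_adj)], pmin(1, off * 45))
  # pairwise-complete n bookkeeping
  traits$V3[1:50] <- NA
  cm2 <- correlation_matrix(traits)
  expect_equal(cm2$n["V3", "V4"], 150)
})

test_that("varimax PCA recovers a planted two-factor structure", {
  set.seed(12)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  traits <- data.frame(a = f1 + rnorm(n, sd = 0.1),
                       b = f1 + rnorm(n, sd = 0.1),
                       c = f1 + rnorm(n, sd = 0.1),
                       d = f2 + rnorm(n, sd = 0.1),
                       e = f2 + rnorm(n, sd = 0.1),
                       f = f2 + rnorm(n, sd = 0.1))
  res <- pca_varimax(traits)
  expect_equal(res$n_retained, 2)
  expect_true(all(res$eigenvalues[1:2] >= 1))
  # after rotation each trait loads >= 0.3 on exactly one component
  expect_equal(unname(rowSums(res$mask)), rep(1, 6))
  on1 <- res$mask[, 1]
  expect_true(identical(sort(rownames(res$mask)[on1]), c("a", "b", "c")) ||
                identical(sort(rownames(res$mask)[on1]), c("d", "e", "f")))
  # duplicated trait pair: one component captures both loadings
  dup <- data.frame(x = f1, y = f1 + rnorm(n, sd = 1e-6),
                    z = rnorm(n), w = rnorm(n))
  res2 <- pca_varimax(dup)
  both <- apply(abs(res2$loadings[c("x", "y"), , drop = FALSE]) > 0.3, 2, all)
  expect_true(any(both))
})
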