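test_that("covariate derivation encodes nested stage binaries", {
  cov <- derive_covariates(toy_clinical())
  expect_equal(cov$gleason, c(1, 2, 3, 4, 5, 2, 3, 1))
  expect_equal(cov$epe, c(0, 1, 1, 1, 0, 1, NA, 0))
  expect_equal(cov$svi, c(0, 0, 1, 1, 0, 0, NA, 0))
  expect_equal(cov$lni, c(0, 1, 0, 0, 1, 0, 0, 0))
  # SVI implies EPE wherever both are observed
  ok <- !is.na(cov$svi)
  expect_true(all(cov$epe[ok][cov$svi[ok] == 1] == 1))
  bad <- toy_clinical(); bad$pt_stage[1] <- "T9"
  expect_error(derive_covariates(bad), "T9")
})

test_that("fit_logistic reproduces the closed-form 2x2 log odds ratio", {
  d <- expand_2x2(30, 10, 10, 30)
  f <- fit_logistic(d$y, d$x)
  expect_equal(f$beta1, log(9), tolerance = 1e-8)
  expect_equal(f$odds_ratio, 9, tolerance = 1e-7)
  expect_true(f$converged)

  # property: over random tables with all cells >= 1 up to N = 200
  set.seed(19)
  for (i in 1:60) {
    n <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.1, 1))[, 1] + 1
    d <- expand_2x2(n[1], n[2], n[3], n[4])
    f <- fit_logistic(d$y, d$x)
    expect_equal(f$beta1, oracle_log_or(n[1], n[2], n[3], n[4]),
                 tolerance = 1e-6)
  }
})

test_that("fit_logistic handles balance, separation and degenerate outcomes", {
  # x independent of y in a balanced design -> beta1 = 0
  d <- expand_2x2(20, 20, 20, 20)
  expect_lt(abs(fit_logistic(d$y, d$x)$beta1), 1e-8)

  # perfect separation -> non-converged flag, not a crash
  y <- c(rep(1, 10), rep(0, 10))
  x <- c(rnorm(10, 5), rnorm(10, -5))
  f <- fit_logistic(y, x)
  expect_false(f$converged)
  expect_true(is.na(f$p_value))

  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "single class")
})

test_that("bh_adjust equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 7)), rep(1, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # q is never below p and is order-preserving
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("feature_association is invariant to feature order and outcome relabeling", {
  set.seed(31)
  co <- generate_cohort(cohort_spec(n_group1 = 80, n_group0 = 70,
                                    n_genes = 30, seed = 3,
                                    planted_effects = c(gene_0005 = 1.5)))
  cov <- derive_covariates(co$clinical)
  y <- as.numeric(co$clinical$group == "AAM")
  r1 <- feature_association(co$expression, y, cov)

  perm <- sample(nrow(co$expression))
  r2 <- feature_association(co$expression[perm, ], y, cov)
  expect_equal(r2[match(r1$feature, r2$feature), "p_value"], r1$p_value,
               tolerance = 1e-9)

  # flipping which group is coded 1 flips the betas
  r3 <- feature_association(co$expression, 1 - y, cov)
  expect_equal(r3$beta1, -r1$beta1, tolerance = 1e-6)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-8)

  # planted gene is the top hit
  expect_equal(r1$feature[which.min(r1$p_value)], "gene_0005")
})

test_that("constant features are flagged and excluded without failing the scan", {
  set.seed(2)
  X <- rbind(gene_a = rnorm(60), flat = rep(3, 60), gene_b = rnorm(60))
  y <- rep(c(1, 0), 30)
  r <- feature_association(X, y)
  expect_false(r$converged[r$feature == "flat"])
  expect_true(is.na(r$q_value[r$feature == "flat"]))
  expect_true(all(!is.na(r$q_value[r$feature != "flat"])))
  expect_error(feature_association(rbind(a = rep(1, 10), b = rep(2, 10)),
                                   rep(c(0, 1), 5)), "all features failed")
})

test_that("covariate adjustment removes grade-driven confounding inflation", {
  # expression depends on grade group only; grade distributions differ by
  # group, so unadjusted tests are anti-conservative while adjustment
  # restores roughly nominal behaviour
  co <- generate_cohort(confounded_cohort_spec(n_genes = 400, seed = 61))
  y <- as.numeric(co$clinical$group == "AAM")
  cov <- derive_covariates(co$clinical)
  unadj <- feature_association(co$expression, y)
  adj <- feature_association(co$expression, y, cov)
  frac_unadj <- mean(unadj$p_value < 0.05, na.rm = TRUE)
  frac_adj <- mean(adj$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac_unadj, 0.2)       # clear type-I inflation without adjustment
  expect_lt(frac_adj, 0.12)        # adjustment restores ~nominal 0.05
  expect_lt(frac_adj, frac_unadj / 2)
})

test_that("DE calling partitions by direction at the q threshold", {
  res <- data.frame(feature = c("a", "b", "c"),
                    beta1 = c(2, -1, 2),
                    q_value = c(1e-6, 1e-7, 0.5))
  de <- call_de_genes(res, 1e-5)
  expect_equal(de$up_group1, "a")
  expect_equal(de$up_group0, "b")
  de_all <- call_de_genes(res, 1)
  expect_setequal(c(de_all$up_group1, de_all$up_group0), c("a", "b", "c"))
  expect_error(call_de_genes(res, 0), "threshold")
})

test_that("wilcoxon_de directions and identical-group behaviour", {
  set.seed(44)
  X <- rbind(up = c(rnorm(10, 2), rnorm(12)),
             same = rep(c(1, 2, 3), length.out = 22),
             dn = c(rnorm(10, -2), rnorm(12)))
  g <- c(rep(1, 10), rep(0, 12))
  r <- wilcoxon_de(X, g)
  expect_equal(r$direction[r$feature == "up"], 1)
  expect_equal(r$direction[r$feature == "dn"], -1)
  # swapping labels flips direction, keeps P
  r2 <- wilcoxon_de(X, 1 - g)
  expect_equal(r2$direction, -r$direction)
  expect_equal(r2$p_value, r$p_value)
  # a gene identical in both groups has P = 1
  X2 <- rbind(flat = rep(5, 8), other = c(1:4, 8:5))
  r3 <- wilcoxon_de(X2, rep(c(1, 0), each = 4))
  expect_equal(r3$p_value[r3$feature == "flat"], 1)
  expect_error(wilcoxon_de(X, rep(1, 22)), "non-empty")
})

test_that("wilcoxon scan at small validation-cohort sizes enriches planted genes among small P", {
  genes <- sprintf("gene_%04d", 1:30)
  sp <- cohort_spec(n_group1 = 37, n_group0 = 233, n_genes = 300,
                    planted_effects = setNames(rep(1.2, 30), genes),
                    seed = 71)
  co <- generate_cohort(sp)
  r <- wilcoxon_de(co$expression, as.numeric(co$clinical$group == "AAM"))
  top <- r$feature[order(r$p_value)][1:50]
  expect_gte(length(intersect(top, genes)), 25)
})

test_that("overlap_de_lists counts intersections and Jaccard", {
  o <- overlap_de_lists(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(o$overlap, 2)
  expect_equal(o$jaccard, 0.5)
  expect_equal(overlap_de_lists(c("A"), c("B"))$overlap, 0)
  expect_equal(overlap_de_lists(character(0), character(0))$jaccard, 0)
  expect_equal(overlap_de_lists(letters[1:5], letters[1:5]),
               list(overlap = 5, jaccard = 1))
})
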