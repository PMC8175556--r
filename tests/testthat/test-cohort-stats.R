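test_that("chi-square test matches published cohort tables and is permutation invariant", {
  gg <- matrix(c(35, 333, 131, 49, 48, 18, 306, 150, 30, 52), ncol = 2)
  r <- chi_square_test(gg)
  expect_equal(round(r$p_value, 3), 0.024)
  expect_equal(r$df, 4)

  pt <- matrix(c(322, 130, 88, 16, 323, 144, 61, 2), ncol = 2)
  expect_equal(round(chi_square_test(pt)$p_value, 3), 0.001)

  # proportional rows: independence holds exactly
  prop <- matrix(c(10, 20, 10, 20), ncol = 2)
  r0 <- chi_square_test(prop)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # invariance under row and column permutation
  set.seed(11)
  for (i in 1:10) {
    tab <- matrix(rpois(12, 20) + 1, nrow = 4)
    p0 <- chi_square_test(tab)$p_value
    expect_equal(chi_square_test(tab[sample(4), ])$p_value, p0)
    expect_equal(chi_square_test(tab[, sample(3)])$p_value, p0)
  }

  # degenerate margins are named
  degen <- matrix(c(0, 5, 0, 7), nrow = 2)
  expect_error(chi_square_test(degen), "row")
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  pn <- matrix(c(21, 27, 20, 24), nrow = 2)
  expect_gte(fisher_exact_test(pn)$p_value, 0.999)

  expect_equal(fisher_exact_test(matrix(1, 2, 2))$p_value, 1)
  r <- fisher_exact_test(matrix(c(5, 0, 0, 5), nrow = 2))
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  expect_error(fisher_exact_test(matrix(1, 3, 2)), "2x2")

  # property: equals brute-force enumeration for random tables with N <= 60
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, nrow = 2)
    if (sum(tab) > 60) next
    expect_equal(fisher_exact_test(tab)$p_value, oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
  }

  # sample odds ratio is ad/bc, not the conditional MLE
  tab <- matrix(c(30, 10, 10, 30), nrow = 2)
  expect_equal(fisher_exact_test(tab)$odds_ratio, 9)
})

test_that("Mann-Whitney U exact path equals enumeration; ties fall back to normal approximation", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)

  # property: exact path equals enumeration oracle for all small splits
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    v <- sample(100, n1 + n2)  # unique values -> no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-10)
  }

  # symmetry: swapping samples leaves the two-sided P unchanged
  x <- rnorm(15); y <- rnorm(12) + 0.5
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)

  # identical multisets give P = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(c(2, 2), c(2, 2))$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("group percentages reproduce the published cohort summaries", {
  expect_equal(round_percent(group_percentage(88 + 16, 596)), 17.4)
  expect_equal(round_percent(group_percentage(63, 556)), 11.3)
  expect_equal(round_percent(group_percentage(89, 596)), 14.9)
  expect_equal(round_percent(group_percentage(54, 556)), 9.7)
  expect_equal(group_percentage(0, 596), 0)
  expect_error(group_percentage(1, 0), "positive")
  expect_error(group_percentage(5, 3), "count")
})

test_that("build_table_one recovers input proportions and applies the right tests", {
  set.seed(21)
  co <- generate_cohort(cohort_spec(n_group1 = 500, n_group0 = 450,
                                    n_genes = 2, seed = 33))
  t1 <- build_table_one(co$clinical,
                        c("grade_group", "pt_stage", "psa"))
  expect_s3_class(t1, "table_one")
  gg_row <- t1$rows[[1]]
  # recovered grade-group proportions close to the generating marginals
  m <- table1_marginals()$grade_group
  expect_equal(unname(gg_row$percent[, "AAM"] / 100), m$AAM, tolerance = 0.08)
  # percentages per group sum to 100
  expect_equal(unname(colSums(gg_row$percent)), c(100, 100))
  # continuous row: median/IQR equal direct computation on non-missing values
  psa_row <- t1$rows[[3]]
  g <- co$clinical$group
  expect_equal(unname(psa_row$median["AAM"]),
               median(co$clinical$psa[g == "AAM"]))
  expect_equal(unname(psa_row$iqr[["EAM"]]),
               unname(quantile(co$clinical$psa[g == "EAM"], c(.25, .75))))
  # missing values excluded with the analysed n reported
  expect_lt(t1$rows[[2]]$n, nrow(co$clinical))
  expect_error(build_table_one(co$clinical, "nope"), "unknown column")
})

test_that("null variables are rarely significant in table-one comparisons", {
  set.seed(5)
  hits <- 0L
  for (r in 1:40) {
    cl <- data.frame(group = rep(c("AAM", "EAM"), c(150, 150)),
                     v = sample(c("a", "b", "c"), 300, replace = TRUE))
    t1 <- build_table_one(cl, list(list(name = "v", type = "categorical")))
    if (t1$rows[[1]]$test$p_value < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 2L)  # >= 95% of null replicates non-significant at 0.01
})

test_that("table_one writers emit parseable TSV and markdown", {
  cl <- toy_clinical()
  t1 <- build_table_one(cl, c("grade_group", "psa"))
  tsv <- tempfile(fileext = ".tsv")
  write_table_one(t1, tsv)
  lines <- readLines(tsv)
  expect_gt(length(lines), 2)
  expect_true(all(lengths(strsplit(lines, "\t")) == length(strsplit(lines[1], "\t")[[1]])))
  md <- tempfile(fileext = ".md")
  write_table_one(t1, md, format = "markdown")
  expect_true(startsWith(readLines(md)[1], "|"))
})
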