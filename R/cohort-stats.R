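#' Validate a contingency table
#'
#' @param counts numeric matrix of non-negative counts, at least 2x2.
#' @return the validated integer matrix (invisibly the same values).
#' @keywords internal
validate_contingency <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("contingency table must be a numeric matrix")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table counts must be non-negative integers")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    lab <- if (!is.null(rownames(counts))) rownames(counts)[bad] else bad
    stop("degenerate contingency table: row(s) with zero total: ",
         paste(lab, collapse = ", "))
  }
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    lab <- if (!is.null(colnames(counts))) colnames(counts)[bad] else bad
    stop("degenerate contingency table: column(s) with zero total: ",
         paste(lab, collapse = ", "))
  }
  counts
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square statistic on an r x c contingency table with
#' df = (r-1)(c-1) and no continuity correction; the P value comes from the
#' chi-square survival function. No Yates correction is applied so that
#' P values on published cohort tables reproduce at their printed precision.
#'
#' @param counts numeric matrix of cell counts (rows = categories,
#'   columns = groups).
#' @return an object of class \code{txc_test}: list with \code{statistic},
#'   \code{p_value}, \code{df}, \code{method}.
#' @examples
#' gg <- matrix(c(35, 333, 131, 49, 48, 18, 306, 150, 30, 52), ncol = 2)
#' chi_square_test(gg)$p_value  # ~0.024
#' @export
chi_square_test <- function(counts) {
  counts <- validate_contingency(counts)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
         df = unname(ht$parameter), method = "Pearson chi-square"),
    class = "txc_test")
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided P value obtained by summing hypergeometric probabilities less
#' than or equal to the probability of the observed table; also returns the
#' sample (unconditional) odds ratio ad/bc.
#'
#' @param counts 2x2 numeric matrix of counts.
#' @return a \code{txc_test} with \code{p_value}, \code{odds_ratio},
#'   \code{method}.
#' @export
fisher_exact_test <- function(counts) {
  counts <- validate_contingency(counts)
  if (nrow(counts) != 2L || ncol(counts) != 2L)
    stop("fisher_exact_test requires a 2x2 table")
  ht <- stats::fisher.test(counts)
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  structure(
    list(statistic = NA_real_, p_value = unname(ht$p.value),
         odds_ratio = unname(or), df = NA_real_, method = "Fisher exact"),
    class = "txc_test")
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise a normal approximation with tie-corrected variance
#' (no continuity correction).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return a \code{txc_test} with the U statistic for \code{x} and the
#'   two-sided \code{p_value}.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("mann_whitney_u: both samples must be non-empty")
  comb <- c(x, y)
  ties <- anyDuplicated(comb) > 0L
  exact <- !ties && length(comb) <= 20L
  # degenerate: every value identical -> zero variance, no evidence
  if (length(unique(comb)) == 1L) {
    return(structure(list(statistic = length(x) * length(y) / 2,
                          p_value = 1, df = NA_real_,
                          method = "Mann-Whitney U (degenerate)"),
                     class = "txc_test"))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
         df = NA_real_,
         method = if (exact) "Mann-Whitney U (exact)"
                  else "Mann-Whitney U (normal approximation)"),
    class = "txc_test")
}

#' @export
print.txc_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat("  statistic:", format(x$statistic), "\n")
  if (!is.null(x$odds_ratio)) cat("  odds ratio:", format(x$odds_ratio), "\n")
  if (!is.na(x$df)) cat("  df:", x$df, "\n")
  cat("  two-sided P:", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Group percentage
#'
#' @param count numerator count (0 <= count <= denom).
#' @param denom denominator count (> 0).
#' @return 100 * count / denom (unrounded; see \code{\link{round_percent}}).
#' @export
group_percentage <- function(count, denom) {
  if (any(denom <= 0)) stop("group_percentage: denominator must be positive")
  if (any(count < 0) || any(count > denom))
    stop("group_percentage: count must lie in [0, denom]")
  100 * count / denom
}

#' Round a percentage to one decimal
#'
#' Uses R's round-half-to-even convention (IEC 60559).
#' @param pct numeric percentages.
#' @param digits decimals kept (default 1).
#' @export
round_percent <- function(pct, digits = 1) round(pct, digits)

# expected counts under independence, for the chi-square-vs-Fisher switch
expected_counts <- function(counts) {
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}

#' Build a Table-1 style cohort comparison
#'
#' For each requested variable, compares the two groups: categorical
#' variables get per-group counts and percentages plus a chi-square test
#' (Fisher exact instead when the table is 2x2 and any expected cell is
#' below 5); continuous variables get median (IQR) per group plus a
#' Mann-Whitney U test. Missing values are excluded per variable (listwise)
#' and the analysed n is reported.
#'
#' @param clinical data frame with one row per sample and a \code{group}
#'   column (two levels).
#' @param vars list of descriptors \code{list(name =, type =)} with type
#'   "categorical" or "continuous"; or a character vector of column names
#'   (types then guessed from the column class).
#' @param group_col name of the grouping column (default "group").
#' @return object of class \code{table_one}.
#' @export
build_table_one <- function(clinical, vars, group_col = "group") {
  if (!group_col %in% names(clinical))
    stop("unknown grouping column: ", group_col)
  grp <- factor(clinical[[group_col]])
  if (nlevels(grp) != 2L) stop("build_table_one requires exactly two groups")
  if (is.character(vars)) {
    vars <- lapply(vars, function(v) {
      col <- clinical[[v]]
      # ordinal scores with few levels (e.g. grade group) are categorical
      cont <- is.numeric(col) && length(unique(col[!is.na(col)])) > 6L
      list(name = v, type = if (cont) "continuous" else "categorical")
    })
  }
  rows <- lapply(vars, function(v) {
    if (!v$name %in% names(clinical)) stop("unknown column: ", v$name)
    val <- clinical[[v$name]]
    keep <- !is.na(val)
    val <- val[keep]; g <- droplevels(grp[keep])
    if (v$type == "categorical") {
      tab <- table(factor(val), g)
      counts <- unclass(tab)
      use_fisher <- nrow(counts) == 2L && ncol(counts) == 2L &&
        any(expected_counts(counts) < 5)
      test <- if (use_fisher) fisher_exact_test(counts)
              else chi_square_test(counts)
      pct <- sweep(counts, 2, colSums(counts), "/") * 100
      list(variable = v$name, type = "categorical", n = length(val),
           counts = counts, percent = pct, test = test)
    } else {
      med <- tapply(val, g, stats::median)
      iqr <- tapply(val, g, function(z)
        stats::quantile(z, c(0.25, 0.75), type = 7))
      test <- mann_whitney_u(val[g == levels(g)[1]], val[g == levels(g)[2]])
      list(variable = v$name, type = "continuous", n = length(val),
           median = med, iqr = iqr, test = test)
    }
  })
  structure(list(rows = rows, groups = levels(grp),
                 n_per_group = as.vector(table(grp))),
            class = "table_one")
}

#' @export
print.table_one <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n_per_group[1], x$groups[2], x$n_per_group[2]))
  for (r in x$rows) {
    cat(sprintf("\n%s (n analysed = %d, %s, P = %s)\n", r$variable, r$n,
                r$test$method, format.pval(r$test$p_value, digits = 3)))
    if (r$type == "categorical") {
      for (i in seq_len(nrow(r$counts))) {
        cat(sprintf("  %-14s %5d (%4.1f)  %5d (%4.1f)\n",
                    rownames(r$counts)[i],
                    r$counts[i, 1], round_percent(r$percent[i, 1]),
                    r$counts[i, 2], round_percent(r$percent[i, 2])))
      }
    } else {
      cat(sprintf("  median (IQR)   %.2f (%.2f, %.2f)  %.2f (%.2f, %.2f)\n",
                  r$median[1], r$iqr[[1]][1], r$iqr[[1]][2],
                  r$median[2], r$iqr[[2]][1], r$iqr[[2]][2]))
    }
  }
  invisible(x)
}

#' Write a table_one object to TSV or Markdown
#'
#' @param x a \code{table_one}.
#' @param path output file.
#' @param format "tsv" or "markdown".
#' @export
write_table_one <- function(x, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  lines <- character(0)
  hdr <- c("variable", "level", paste0(x$groups[1], "_n"),
           paste0(x$groups[1], "_pct"), paste0(x$groups[2], "_n"),
           paste0(x$groups[2], "_pct"), "n_analysed", "test", "p_value")
  body <- list()
  for (r in x$rows) {
    if (r$type == "categorical") {
      for (i in seq_len(nrow(r$counts))) {
        body[[length(body) + 1L]] <- c(
          r$variable, rownames(r$counts)[i],
          r$counts[i, 1], round_percent(r$percent[i, 1]),
          r$counts[i, 2], round_percent(r$percent[i, 2]),
          r$n, r$test$method, format(r$test$p_value))
      }
    } else {
      body[[length(body) + 1L]] <- c(
        r$variable, "median(IQR)",
        sprintf("%.3g (%.3g-%.3g)", r$median[1], r$iqr[[1]][1], r$iqr[[1]][2]), "",
        sprintf("%.3g (%.3g-%.3g)", r$median[2], r$iqr[[2]][1], r$iqr[[2]][2]), "",
        r$n, r$test$method, format(r$test$p_value))
    }
  }
  mat <- do.call(rbind, body)
  if (format == "tsv") {
    lines <- c(paste(hdr, collapse = "\t"),
               apply(mat, 1, paste, collapse = "\t"))
  } else {
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
               apply(mat, 1, function(z)
                 paste0("| ", paste(z, collapse = " | "), " |")))
  }
  writeLines(lines, path)
  invisible(path)
}
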