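#' Derive stage covariates from a clinical table
#'
#' Builds the covariate set of the race-association model from clinical
#' columns: Gleason grade group as a single ordinal numeric term (1-5), and
#' pathologic stage decomposed into nested binaries - extraprostatic
#' extension (EPE, pT >= T3a), seminal vesicle invasion (SVI, pT >= T3b) and
#' lymph-node involvement (LNI, pN = N1). T4 contributes to both EPE and
#' SVI. An unstaged pN (NX) is treated as node-negative; a missing pT yields
#' missing EPE/SVI (samples are then dropped per-run by the association
#' scan).
#'
#' @param clinical data frame with grade_group, pt_stage, pn_stage columns.
#' @return data frame with numeric columns gleason, epe, svi, lni, row per
#'   sample.
#' @export
derive_covariates <- function(clinical) {
  pt <- as.character(clinical$pt_stage)
  known <- c("T2", "T3a", "T3b", "T4")
  bad <- setdiff(unique(pt[!is.na(pt)]), known)
  if (length(bad)) stop("unknown pT stage codes: ", paste(bad, collapse = ", "))
  pn <- as.character(clinical$pn_stage)
  badn <- setdiff(unique(pn[!is.na(pn)]), c("N0", "N1", "NX"))
  if (length(badn)) stop("unknown pN stage codes: ", paste(badn, collapse = ", "))
  data.frame(
    gleason = as.numeric(clinical$grade_group),
    epe = as.numeric(pt %in% c("T3a", "T3b", "T4")) + ifelse(is.na(pt), NA, 0),
    svi = as.numeric(pt %in% c("T3b", "T4")) + ifelse(is.na(pt), NA, 0),
    lni = as.numeric(!is.na(pn) & pn == "N1"),
    row.names = clinical$sample_id)
}

#' Fit a single covariate-adjusted logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on one feature
#' plus optional covariates, fit by iteratively reweighted least squares
#' (via \code{stats::glm.fit}, epsilon 1e-10, at most 100 iterations).
#' Reports the Wald P value for the feature coefficient. Complete or
#' quasi-complete separation is detected (fitted probabilities pinned at
#' 0/1 with an exploding coefficient) and flagged as non-converged rather
#' than crashing.
#'
#' @param y binary outcome (0/1 or logical) per sample.
#' @param x numeric feature values per sample.
#' @param cov optional data frame / matrix of numeric covariates.
#' @return object of class \code{logistic_fit}: coefficients, standard
#'   errors, \code{beta1}, \code{odds_ratio}, \code{p_value}, \code{n_used},
#'   \code{converged}.
#' @export
fit_logistic <- function(y, x, cov = NULL) {
  y <- as.numeric(y)
  X <- cbind(intercept = 1, feature = as.numeric(x))
  if (!is.null(cov)) X <- cbind(X, as.matrix(cov))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("outcome has a single class after removing missing values")
  if (nrow(X) <= ncol(X))
    stop("more parameters than observations")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  # covariance from the final IRLS weighted least squares
  p <- ncol(X)
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  covmat <- tryCatch(chol2inv(Rmat), error = function(e) matrix(NA, p, p))
  se <- sqrt(diag(covmat))
  names(se) <- names(beta)
  mu <- fit$fitted.values
  # separation: some fitted probabilities pinned at 0/1 together with an
  # exploding coefficient, an exploding Wald SE, or a perfect fit
  pinned <- any(mu < 1e-8) || any(mu > 1 - 1e-8)
  separated <- (pinned && (abs(beta["feature"]) > 10 || se["feature"] > 10)) ||
    fit$deviance < 1e-6
  converged <- fit$converged && !separated && all(is.finite(beta))
  z <- beta["feature"] / se["feature"]
  pval <- if (converged) 2 * stats::pnorm(-abs(z)) else NA_real_
  structure(list(coefficients = beta, se = se,
                 beta1 = unname(beta["feature"]),
                 odds_ratio = unname(exp(beta["feature"])),
                 p_value = unname(pval), n_used = nrow(X),
                 converged = converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, %s)\n", x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  feature beta = %.4f (OR %.3f), Wald P = %s\n",
              x$beta1, x$odds_ratio, format.pval(x$p_value)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up FDR adjustment: q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / j, capped at 1, order-preserving with the input.
#'
#' @param p numeric vector of P values in [0, 1]; NAs pass through.
#' @return vector of q values, same order as input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("P values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-feature covariate-adjusted association scan
#'
#' Fits one logistic model per feature (gene expression, pathway score or
#' drug score) against a binary group outcome, adjusting for the supplied
#' covariates, then BH-adjusts the Wald P values across all features that
#' produced one. Samples with any missing covariate are dropped once, up
#' front, so every feature is fit on the same n. Constant or non-converged
#' features are flagged and excluded from the BH family (they contribute no
#' P value); the scan fails only if every feature fails.
#'
#' @param X features x samples numeric matrix.
#' @param outcome binary outcome per sample (1 = group of interest).
#' @param cov optional covariate data frame aligned to samples.
#' @return object of class \code{assoc_result}: data frame with feature,
#'   beta1, odds_ratio, p_value, q_value, n_used, converged.
#' @export
feature_association <- function(X, outcome, cov = NULL) {
  if (!is.matrix(X) || nrow(X) < 2L)
    stop("need a features x samples matrix with at least 2 features")
  if (ncol(X) != length(outcome))
    stop("outcome length does not match number of samples")
  outcome <- as.numeric(outcome)
  keep <- !is.na(outcome)
  if (!is.null(cov)) keep <- keep & stats::complete.cases(cov)
  X <- X[, keep, drop = FALSE]
  outcome <- outcome[keep]
  covm <- if (is.null(cov)) NULL else as.matrix(cov)[keep, , drop = FALSE]
  if (!is.null(covm)) {
    constant <- apply(covm, 2, function(v) length(unique(v)) < 2L)
    if (any(constant)) {
      warning("dropping constant covariate(s): ",
              paste(colnames(covm)[constant], collapse = ", "))
      covm <- covm[, !constant, drop = FALSE]
      if (ncol(covm) == 0L) covm <- NULL
    }
  }

  base <- cbind(intercept = 1, feature = 0)
  fits <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    if (stats::sd(xi) == 0 || anyNA(xi)) {
      fits[[i]] <- list(beta1 = NA_real_, odds_ratio = NA_real_,
                        p_value = NA_real_, n_used = 0L, converged = FALSE)
      next
    }
    f <- tryCatch(fit_logistic(outcome, xi, covm),
                  error = function(e) NULL)
    fits[[i]] <- if (is.null(f))
      list(beta1 = NA_real_, odds_ratio = NA_real_, p_value = NA_real_,
           n_used = 0L, converged = FALSE) else f
  }
  res <- data.frame(
    feature = rownames(X),
    beta1 = vapply(fits, function(f) f$beta1, 0),
    odds_ratio = vapply(fits, function(f) f$odds_ratio, 0),
    p_value = vapply(fits, function(f) f$p_value, 0),
    n_used = vapply(fits, function(f) as.integer(f$n_used), 0L),
    converged = vapply(fits, function(f) f$converged, TRUE),
    stringsAsFactors = FALSE)
  if (all(is.na(res$p_value))) stop("all features failed to fit")
  res$q_value <- bh_adjust(res$p_value)
  res <- res[, c("feature", "beta1", "odds_ratio", "p_value", "q_value",
                 "n_used", "converged")]
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' @export
print.assoc_result <- function(x, q_threshold = 0.05, ...) {
  n_ok <- sum(x$converged)
  cat(sprintf("Association scan: %d features (%d converged), %d at q < %g\n",
              nrow(x), n_ok, sum(x$q_value < q_threshold, na.rm = TRUE),
              q_threshold))
  top <- x[order(x$p_value), ]
  print.data.frame(utils::head(top, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.assoc_result <- function(object, q_threshold = 0.05, ...) {
  called <- call_de_genes(object, q_threshold)
  list(n_features = nrow(object),
       n_converged = sum(object$converged),
       n_significant = sum(object$q_value < q_threshold, na.rm = TRUE),
       up_group1 = called$up_group1, up_group0 = called$up_group0)
}

#' Call differentially expressed features
#'
#' Features with q below the threshold, split by direction of the feature
#' coefficient (positive: higher in the group coded 1).
#'
#' @param res an \code{assoc_result} (or data frame with feature, beta1,
#'   q_value).
#' @param q_threshold FDR threshold in (0, 1); the published genome-wide
#'   scan used 1e-5.
#' @return list with character vectors \code{up_group1}, \code{up_group0}.
#' @export
call_de_genes <- function(res, q_threshold = 1e-5) {
  if (q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must lie in (0, 1]")
  hit <- !is.na(res$q_value) & res$q_value < q_threshold
  list(up_group1 = res$feature[hit & res$beta1 > 0],
       up_group0 = res$feature[hit & res$beta1 < 0])
}

#' Rank-test differential expression
#'
#' Per-gene two-sided Mann-Whitney U test between groups with direction
#' from the group-mean difference, BH-adjusted across genes. This is the
#' unadjusted rank-based scan used for validation cohorts that lack the
#' covariate detail of the main model.
#'
#' @param expr genes x samples matrix.
#' @param groups binary labels per sample (1 = group of interest).
#' @return data frame: feature, direction (+1/-1/0), p_value, q_value.
#' @export
wilcoxon_de <- function(expr, groups) {
  groups <- as.numeric(groups)
  if (sum(groups == 1) == 0L || sum(groups == 0) == 0L)
    stop("both groups must be non-empty")
  g1 <- groups == 1
  p <- numeric(nrow(expr)); dir <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    t <- mann_whitney_u(expr[i, g1], expr[i, !g1])
    p[i] <- t$p_value
    dir[i] <- sign(mean(expr[i, g1]) - mean(expr[i, !g1]))
  }
  data.frame(feature = rownames(expr), direction = dir, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Overlap between two gene lists
#'
#' @param listA,listB character vectors.
#' @return list with \code{overlap} (|A intersect B|) and \code{jaccard}
#'   (|A intersect B| / |A union B|; 0 for two empty lists).
#' @export
overlap_de_lists <- function(listA, listB) {
  a <- unique(listA); b <- unique(listB)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(overlap = inter, jaccard = if (uni == 0) 0 else inter / uni)
}
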