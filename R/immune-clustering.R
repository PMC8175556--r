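#' Adverse pathology flag
#'
#' Per-sample indicator of adverse pathology: grade group >= 3 and/or
#' node-positive (pN = N1) and/or pT3-4 disease. An unstaged pN (NX or
#' missing) does not count as node-positive; a missing pT does not meet the
#' stage criterion (the sample can still be flagged through grade or nodes).
#'
#' @param clinical data frame with grade_group, pt_stage, pn_stage.
#' @return named logical vector per sample.
#' @export
derive_adverse_pathology <- function(clinical) {
  pt <- as.character(clinical$pt_stage)
  bad <- setdiff(unique(pt[!is.na(pt)]), c("T2", "T3a", "T3b", "T4"))
  if (length(bad)) stop("unknown pT stage codes: ", paste(bad, collapse = ", "))
  pn <- as.character(clinical$pn_stage)
  badn <- setdiff(unique(pn[!is.na(pn)]), c("N0", "N1", "NX"))
  if (length(badn)) stop("unknown pN stage codes: ", paste(badn, collapse = ", "))
  flag <- (!is.na(clinical$grade_group) & clinical$grade_group >= 3) |
    (!is.na(pn) & pn == "N1") |
    (!is.na(pt) & pt %in% c("T3a", "T3b", "T4"))
  names(flag) <- clinical$sample_id
  flag
}

# k-means++ seeding: spread initial centers by squared-distance sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) == 0) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

# default base clusterer: k-means with k-means++ init, multiple restarts
kmeanspp_cluster <- function(x, k, nstart = 10) {
  best <- NULL
  for (r in seq_len(nstart)) {
    cen <- kmeanspp_centers(x, k)
    if (nrow(unique(cen)) < k) next
    km <- tryCatch(stats::kmeans(x, centers = cen, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) rep(1L, nrow(x)) else best$cluster
}

#' Consensus clustering over a gene panel
#'
#' Repeated clustering on subsampled samples: for each candidate k, samples
#' are subsampled \code{n_resamples} times at \code{subsample_frac}, the
#' base clusterer (k-means with k-means++ seeding and 10 restarts, on
#' z-scored panel genes) is run, and the consensus matrix records, for each
#' sample pair, the co-assignment count divided by the co-subsample count.
#' Final labels come from average-linkage hierarchical clustering of
#' (1 - consensus) cut at k. The number of clusters is selected by the
#' proportion of ambiguous clustering (PAC): the fraction of off-diagonal
#' consensus entries strictly inside \code{ambiguity_bounds}; the k with the
#' smallest PAC wins (ties to the smaller k). Deterministic for a fixed
#' seed.
#'
#' @param expr panel genes x samples matrix (>= 2 genes).
#' @param k_range integer candidate cluster counts, within [2, n/2].
#' @param n_resamples subsampling repeats per k (default 500).
#' @param subsample_frac fraction of samples per resample (default 0.8).
#' @param seed integer seed.
#' @param ambiguity_bounds PAC window (default c(0.1, 0.9)).
#' @param clusterer base clustering function(data, k) -> integer labels;
#'   default the internal k-means++ clusterer.
#' @return object of class \code{consensus_result}: selected \code{k},
#'   \code{labels}, \code{consensus} (samples x samples), \code{pac} per k,
#'   \code{item_consensus} per sample, \code{per_k} detail list,
#'   \code{degenerate} flag.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, n_resamples = 500,
                              subsample_frac = 0.8, seed = 1,
                              ambiguity_bounds = c(0.1, 0.9),
                              clusterer = NULL) {
  if (nrow(expr) < 2L) stop("panel must contain at least 2 genes")
  n <- ncol(expr)
  if (any(k_range < 2) || any(k_range > n / 2))
    stop("k_range must lie within [2, n/2]")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must lie in (0, 1]")
  if (is.null(clusterer)) clusterer <- kmeanspp_cluster
  set.seed(seed)
  x <- t(scale_genes(expr))   # samples x genes, z-scored per gene
  ids <- colnames(expr)
  m_sub <- max(2L, floor(subsample_frac * n))

  per_k <- list()
  pac <- setNames(numeric(length(k_range)), as.character(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n)     # co-assignment counts
    tog <- matrix(0, n, n)    # co-subsample counts
    for (b in seq_len(n_resamples)) {
      s <- if (m_sub == n) seq_len(n) else sort(sample.int(n, m_sub))
      lab <- clusterer(x[s, , drop = FALSE], k)
      tog[s, s] <- tog[s, s] + 1
      same <- outer(lab, lab, "==")
      co[s, s] <- co[s, s] + same
    }
    cons <- matrix(0, n, n)
    pos <- tog > 0
    cons[pos] <- co[pos] / tog[pos]
    if (any(!pos[upper.tri(pos)]))
      warning("some sample pairs were never co-subsampled; consensus set to 0")
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels <- stats::cutree(hc, k = k)
    off <- cons[upper.tri(cons)]
    pac[ki] <- mean(off > ambiguity_bounds[1] & off < ambiguity_bounds[2])
    per_k[[as.character(k)]] <- list(k = k, consensus = cons,
                                     labels = labels, pac = pac[ki])
  }
  k_sel <- k_range[which.min(pac)]   # ties resolve to the smaller k
  best <- per_k[[as.character(k_sel)]]
  item_cons <- vapply(seq_len(n), function(i) {
    members <- setdiff(which(best$labels == best$labels[i]), i)
    if (length(members) == 0L) return(1)
    mean(best$consensus[i, members])
  }, 0)
  names(item_cons) <- ids
  degenerate <- all(best$consensus >= 0.99)
  structure(list(k = k_sel, labels = best$labels,
                 consensus = best$consensus, pac = pac,
                 item_consensus = item_cons, per_k = per_k,
                 n_resamples = n_resamples,
                 subsample_frac = subsample_frac,
                 degenerate = degenerate, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("Consensus clustering: selected k = %d (PAC %s)\n", x$k,
              paste(sprintf("k=%s: %.3f", names(x$pac), x$pac),
                    collapse = ", ")))
  cat("  cluster sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                                collapse = ", "), "\n")
  if (x$degenerate) cat("  WARNING: degenerate consensus (all entries ~1)\n")
  invisible(x)
}

#' Cluster enrichment for a binary annotation
#'
#' For each cluster: the proportion of flagged samples plus the Fisher exact
#' P of the (in-cluster vs out-of-cluster) x (flagged vs not) 2x2 table.
#'
#' @param labels cluster ids per sample (>= 2 clusters).
#' @param flags logical annotation per sample (e.g. adverse pathology).
#' @return data frame (cluster, n, n_flagged, proportion, p_value) with the
#'   2x2 tables in attribute \code{tables}.
#' @export
cluster_enrichment <- function(labels, flags) {
  if (length(unique(labels)) < 2L)
    stop("cluster_enrichment requires at least 2 clusters")
  if (length(labels) != length(flags))
    stop("labels and flags must have equal length")
  flags <- as.logical(flags)
  cl <- sort(unique(labels))
  tabs <- list()
  rows <- lapply(cl, function(cc) {
    inc <- labels == cc
    tab <- matrix(c(sum(inc & flags), sum(inc & !flags),
                    sum(!inc & flags), sum(!inc & !flags)),
                  nrow = 2,
                  dimnames = list(c("flagged", "not"), c("in", "out")))
    p <- stats::fisher.test(tab)$p.value
    tabs[[as.character(cc)]] <<- tab
    data.frame(cluster = cc, n = sum(inc), n_flagged = sum(inc & flags),
               proportion = sum(inc & flags) / sum(inc), p_value = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tabs
  out
}

#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
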