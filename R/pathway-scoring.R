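#' Z-score genes across samples
#'
#' Scales every row (gene) of an expression matrix to mean 0, sd 1 across
#' samples (sd with denominator n-1). Constant genes cannot be scaled and
#' are set to all-zero with a warning rather than aborting, so gene sets
#' containing flat probes do not kill a run.
#'
#' @param expr genes x samples numeric matrix.
#' @return matrix of the same shape, rows standardized.
#' @export
scale_genes <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (ncol(expr) < 2L) stop("scaling needs at least 2 samples")
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  flat <- sd == 0 | !is.finite(sd)
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) scaled to zero: ",
            paste(utils::head(rownames(expr)[flat], 5), collapse = ", "))
    sd[flat] <- 1
  }
  z <- (expr - mu) / sd
  z[flat, ] <- 0
  z
}

#' Pathway activity score
#'
#' Per-sample mean of z-scored expression over a gene set's genes. Scaling
#' is per gene across all samples (both groups pooled), so within-set and
#' genome-wide scaling coincide. Set genes absent from the matrix are
#' dropped (with a message); a set with zero coverage is an error.
#'
#' @param expr genes x samples numeric matrix (unscaled log expression).
#' @param genes character vector of set member gene ids.
#' @param name set name, used in messages.
#' @return named per-sample numeric vector with attribute \code{n_genes_used}.
#' @export
pathway_score <- function(expr, genes, name = "gene set") {
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L)
    stop("gene set '", name, "' has no genes in the expression matrix")
  if (length(present) < length(genes))
    message("gene set '", name, "': ", length(present), "/", length(genes),
            " genes present")
  z <- scale_genes(expr[present, , drop = FALSE])
  out <- colMeans(z)
  attr(out, "n_genes_used") <- length(present)
  out
}

#' Score all gene sets of a collection
#'
#' @param expr genes x samples matrix.
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @return score matrix, sets x samples.
#' @export
pathway_score_matrix <- function(expr, sets) {
  if (length(sets) == 0L) stop("no gene sets supplied")
  rows <- lapply(names(sets), function(nm)
    pathway_score(expr, sets[[nm]], name = nm))
  out <- do.call(rbind, rows)
  rownames(out) <- names(sets)
  out
}

#' Weighted signature score
#'
#' Per-sample weighted mean of expression over a signature's genes:
#' sum(w_g * x_gs) / sum(|w_g|) over the genes present. With all weights
#' equal this reduces to the plain mean. Expression is optionally z-scored
#' per gene first (the signature's \code{scale} policy).
#'
#' @param expr genes x samples matrix.
#' @param signature \code{list(name =, weights = named numeric, scale = flag)}.
#' @return named per-sample numeric vector.
#' @export
signature_score <- function(expr, signature) {
  w <- signature$weights
  if (is.null(w) || length(w) == 0L || is.null(names(w)))
    stop("signature '", signature$name, "' has no named weights")
  if (any(!is.finite(w))) stop("signature '", signature$name,
                               "' has non-finite weights")
  present <- intersect(names(w), rownames(expr))
  if (length(present) == 0L)
    stop("signature '", signature$name,
         "' has no genes in the expression matrix")
  w <- w[present]
  denom <- sum(abs(w))
  if (denom == 0) stop("signature '", signature$name,
                       "': weights sum to zero in absolute value")
  x <- expr[present, , drop = FALSE]
  if (isTRUE(signature$scale)) x <- scale_genes(x)
  colSums(w * x) / denom
}

#' Average genomic risk (AGR)
#'
#' Per-sample unweighted mean over a panel of signature scores (the
#' published usage averages 19 prognostic signatures, excluding the
#' commercial Decipher score). Because published signatures live on
#' incommensurate scales, each signature row is z-scored across samples
#' before averaging by default; pass \code{standardize = FALSE} when scores
#' are already on a common scale.
#'
#' @param sig_scores signatures x samples numeric matrix.
#' @param standardize z-score each signature across samples first
#'   (default TRUE).
#' @return named per-sample numeric vector.
#' @export
average_genomic_risk <- function(sig_scores, standardize = TRUE) {
  if (!is.matrix(sig_scores) || nrow(sig_scores) < 1L)
    stop("sig_scores must be a matrix with at least one signature row")
  if (anyNA(sig_scores))
    stop("missing signature scores: every signature must cover every sample")
  if (standardize) sig_scores <- scale_genes(sig_scores)
  colMeans(sig_scores)
}
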