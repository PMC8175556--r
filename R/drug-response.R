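#' Correlation-weighted drug response score (DRS)
#'
#' Per-sample score for one drug: DRS_s = sum_g(Cor_g * x_gs) / sum_g(Cor_g)
#' over the model genes present in the matrix, where Cor_g is the gene's
#' correlation with cell-line drug sensitivity (IC50-derived, from the
#' NCI-60 panel) and x_gs is the unscaled expression. The signed-sum
#' denominator follows the published definition; because sign-mixed models
#' can make it vanish, a near-zero denominator is an error naming the drug,
#' and \code{normalize = "abs"} offers an explicit alternative dividing by
#' sum(|Cor|).
#'
#' @param expr genes x samples numeric matrix.
#' @param model \code{list(drug =, correlations = named numeric in [-1, 1])}.
#' @param normalize "signed" (default, sum of Cor) or "abs" (sum of |Cor|).
#' @return named per-sample numeric vector with attribute
#'   \code{n_genes_used}.
#' @export
compute_drs <- function(expr, model, normalize = c("signed", "abs")) {
  normalize <- match.arg(normalize)
  cor <- model$correlations
  if (is.null(cor) || length(cor) == 0L || is.null(names(cor)))
    stop("drug model '", model$drug, "' has no named correlations")
  if (any(abs(cor) > 1 | !is.finite(cor)))
    stop("drug model '", model$drug, "' has correlations outside [-1, 1]")
  present <- intersect(names(cor), rownames(expr))
  if (length(present) == 0L)
    stop("drug model '", model$drug,
         "' has no genes in the expression matrix")
  cor <- cor[present]
  denom <- if (normalize == "signed") sum(cor) else sum(abs(cor))
  if (abs(denom) < 1e-9)
    stop("drug model '", model$drug,
         "': sum of correlations is (near) zero; cannot normalize")
  out <- colSums(cor * expr[present, , drop = FALSE]) / denom
  attr(out, "n_genes_used") <- length(present)
  out
}

#' Drug response score matrix
#'
#' One row per drug via \code{\link{compute_drs}}. A drug whose model fails
#' (zero coverage, degenerate denominator) is recorded and skipped; the run
#' aborts only if every drug fails.
#'
#' @param expr genes x samples matrix.
#' @param models list of drug models; drug names must be unique.
#' @param normalize passed to \code{\link{compute_drs}}.
#' @return drugs x samples matrix with attribute \code{failed}: named list
#'   of error messages for skipped drugs.
#' @export
drs_matrix <- function(expr, models, normalize = "signed") {
  if (length(models) == 0L) stop("no drug models supplied")
  drugs <- vapply(models, function(m) m$drug, "")
  if (anyDuplicated(drugs))
    stop("duplicate drug names: ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
  rows <- vector("list", length(models))
  failed <- list()
  for (i in seq_along(models)) {
    r <- tryCatch(compute_drs(expr, models[[i]], normalize),
                  error = function(e) e)
    if (inherits(r, "error")) failed[[drugs[i]]] <- conditionMessage(r)
    else rows[[i]] <- r
  }
  ok <- !vapply(rows, is.null, TRUE)
  if (!any(ok)) stop("all drug models failed to score")
  out <- do.call(rbind, rows[ok])
  rownames(out) <- drugs[ok]
  attr(out, "failed") <- failed
  out
}

#' Compare drug response scores between groups
#'
#' Covariate-adjusted logistic association of each drug's per-sample score
#' with the binary group outcome; delegates to
#' \code{\link{feature_association}} with drugs as features.
#'
#' @param drs drugs x samples matrix.
#' @param outcome binary group labels per sample.
#' @param cov optional covariate data frame.
#' @return an \code{assoc_result}, one row per drug.
#' @export
compare_drs <- function(drs, outcome, cov = NULL) {
  feature_association(drs, outcome, cov)
}
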