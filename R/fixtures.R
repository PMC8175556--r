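#' Simulate plausible drug response models
#'
#' Draws, for each drug, a random gene panel with correlation weights in
#' [-1, 1] whose signed sum is kept away from zero (so the published
#' signed-sum normalization is well defined). Gene selection against real
#' cell-line sensitivity data is an input-preparation step upstream of this
#' package; these synthetic models exercise the scorer.
#'
#' @param n_drugs number of models.
#' @param genes pool of gene ids to draw from.
#' @param genes_per_drug panel size per drug (default 20).
#' @param seed integer seed.
#' @return list of drug models for \code{\link{drs_matrix}}.
#' @export
simulate_drug_models <- function(n_drugs, genes, genes_per_drug = 20,
                                 seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_drugs), function(i) {
    g <- sample(genes, genes_per_drug)
    repeat {
      cor <- stats::runif(genes_per_drug, -1, 1)
      if (abs(sum(cor)) > 0.5) break
    }
    names(cor) <- g
    list(drug = sprintf("drug_%03d", i), correlations = cor)
  })
}

#' Simulate gene sets
#'
#' Random non-overlapping-name gene sets drawn from a gene pool, for
#' exercising pathway scoring.
#'
#' @param n_sets number of sets.
#' @param genes pool of gene ids.
#' @param set_size genes per set (recycled).
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(n_sets, genes, set_size = 30, seed = 1) {
  set.seed(seed)
  set_size <- rep_len(set_size, n_sets)
  out <- lapply(seq_len(n_sets), function(i) sample(genes, set_size[i]))
  names(out) <- sprintf("set_%02d", seq_len(n_sets))
  out
}

#' Simulate an immune gene panel
#'
#' A synthetic stand-in for a tumor microenvironment / immune-response gene
#' panel (the published panel has 124 members and is not redistributable
#' here): simply a deterministic sample of gene ids of the requested size.
#'
#' @param genes pool of gene ids.
#' @param size panel size (default 124).
#' @param seed integer seed.
#' @return character vector of gene ids.
#' @export
simulate_immune_panel <- function(genes, size = 124, seed = 1) {
  set.seed(seed)
  sample(genes, min(size, length(genes)))
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write drug models as JSON
#' @param models list of drug models.
#' @param path output file.
#' @export
write_drug_models <- function(models, path) {
  jsonlite::write_json(
    lapply(models, function(m)
      list(drug = m$drug, correlations = as.list(m$correlations))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
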