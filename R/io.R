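#' Read an expression matrix from TSV
#'
#' Expects a header of sample ids with the first column holding feature ids.
#' Ragged rows, duplicate feature ids and non-numeric cells are hard errors
#' reported with their line number.
#'
#' @param path TSV file.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(parts[[1]])
  if (width < 2L) stop("line 1: header must name at least one sample")
  bad <- which(lengths(parts) != width)
  if (length(bad))
    stop("ragged row(s) at line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  samples <- parts[[1]][-1]
  ids <- vapply(parts[-1], `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  vals <- vapply(parts[-1], function(p) {
    suppressWarnings(as.numeric(p[-1]))
  }, numeric(width - 1L))
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = width - 1L)
  nas <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(nas)) {
    stop("non-numeric cell at line ", nas[1, 1] + 1L,
         ", column ", nas[1, 2] + 1L)
  }
  dimnames(mat) <- list(ids, samples)
  mat
}

#' Write an expression matrix as TSV
#'
#' Full-precision numeric output (17 significant digits, round-trips through
#' \code{read_expression}), first column \code{feature_id}, trailing newline.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  hdr <- paste(c("feature_id", colnames(expr)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i)
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t"),
    "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' @param path CSV file with at least sample_id and group columns.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cl$sample_id))
    stop("duplicate sample ids in clinical table")
  cl
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes. Empty
#' sets are an error with the line number; duplicate genes within a set are
#' de-duplicated with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("line ", i, ": GMT line needs a name, description and >= 1 gene")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("line ", i, ": gene set '", f[1], "' is empty")
    if (anyDuplicated(genes)) {
      warning("line ", i, ": duplicate genes in set '", f[1], "' de-duplicated")
      genes <- unique(genes)
    }
    if (f[1] %in% names(sets)) stop("line ", i, ": duplicate set name '", f[1], "'")
    sets[[f[1]]] <- genes
  }
  sets
}

#' Read signature models from JSON
#'
#' Expects an array of objects \code{{name, weights: {gene: w}, scale: bool}}.
#'
#' @param path JSON file.
#' @return list of signature models.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path)
  lapply(raw, function(s) {
    if (is.null(s$name) || is.null(s$weights))
      stop("signature entries need 'name' and 'weights'")
    list(name = s$name,
         weights = unlist(s$weights),
         scale = isTRUE(s$scale))
  })
}

#' Read drug response models from JSON
#'
#' Expects an array of objects \code{{drug, correlations: {gene: cor}}}.
#'
#' @param path JSON file.
#' @return list of drug models.
#' @export
read_drug_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m) {
    if (is.null(m$drug) || is.null(m$correlations))
      stop("drug model entries need 'drug' and 'correlations'")
    list(drug = m$drug, correlations = unlist(m$correlations))
  })
}

#' Read a gene panel
#'
#' One gene id per line, or a GMT file (all sets pooled).
#'
#' @param path text or GMT file.
#' @return character vector of gene ids.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (any(grepl("\t", lines, fixed = TRUE)))
    unique(unlist(read_gmt(path), use.names = FALSE))
  else unique(trimws(lines))
}

#' Write a score matrix (scores x samples) as TSV
#' @param scores numeric matrix.
#' @param path output file.
#' @param id_col name of the first column (default "score").
#' @export
write_scores <- function(scores, path, id_col = "score") {
  hdr <- paste(c(id_col, colnames(scores)), collapse = "\t")
  body <- vapply(seq_len(nrow(scores)), function(i)
    paste(c(rownames(scores)[i], sprintf("%.17g", scores[i, ])),
          collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an association result as TSV
#' @param res an \code{assoc_result} data frame.
#' @param path output file.
#' @export
write_assoc <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Validates file existence and thresholds up front; referenced inputs must
#' exist before any stage runs.
#'
#' @param expression path to expression TSV (required).
#' @param clinical path to clinical CSV (required).
#' @param gene_sets optional GMT of pathway gene sets.
#' @param signatures optional JSON of signature models.
#' @param drug_models optional JSON of drug response models.
#' @param panel optional immune gene panel file.
#' @param outcome_col clinical column holding the group label.
#' @param positive_label level coded 1 in the logistic models.
#' @param q_threshold FDR threshold for DE calls (default 1e-5).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return validated \code{run_config} object.
#' @export
run_config <- function(expression, clinical, gene_sets = NULL,
                       signatures = NULL, drug_models = NULL, panel = NULL,
                       outcome_col = "group", positive_label = "AAM",
                       q_threshold = 1e-5, seed = 1, out_dir = "txcohort_run") {
  paths <- c(expression = expression, clinical = clinical,
             gene_sets = gene_sets, signatures = signatures,
             drug_models = drug_models, panel = panel)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)")
  structure(list(expression = expression, clinical = clinical,
                 gene_sets = gene_sets, signatures = signatures,
                 drug_models = drug_models, panel = panel,
                 outcome_col = outcome_col, positive_label = positive_label,
                 q_threshold = q_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, fun) {
  tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full comparison pipeline
#'
#' Executes, in order: cohort table-one, pathway scoring (+ score
#' association), genome-wide gene association and DE calling, drug response
#' scoring (+ comparison), immune-panel consensus clustering with adverse
#' pathology enrichment, and a JSON summary. The clinical table is the
#' master sample list: expression columns are reordered to match it and any
#' mismatch in the sample sets is a hard error (no silent intersection).
#' Every run writes a provenance record (input checksums, seed, package
#' version) and is deterministic given the seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  clinical <- stage("read_clinical", function() read_clinical(config$clinical))
  expr <- stage("read_expression", function() read_expression(config$expression))
  if (!setequal(colnames(expr), clinical$sample_id))
    stop("pipeline stage 'align' failed: expression and clinical sample sets ",
         "differ (", length(setdiff(clinical$sample_id, colnames(expr))),
         " missing from expression, ",
         length(setdiff(colnames(expr), clinical$sample_id)), " extra)",
         call. = FALSE)
  expr <- expr[, clinical$sample_id, drop = FALSE]

  outcome <- as.numeric(clinical[[config$outcome_col]] == config$positive_label)
  if (length(unique(outcome)) < 2L)
    stop("outcome column has a single level")
  cov <- stage("covariates", function() derive_covariates(clinical))

  t1 <- stage("table_one", function()
    build_table_one(clinical,
                    intersect(c("grade_group", "pt_stage", "pn_stage",
                                "capra_s", "psa"), names(clinical)),
                    group_col = config$outcome_col))
  write_table_one(t1, file.path(config$out_dir, "table_one.tsv"))

  summary_list <- list(n_samples = ncol(expr), n_genes = nrow(expr),
                       n_group1 = sum(outcome == 1),
                       n_group0 = sum(outcome == 0))

  if (!is.null(config$gene_sets)) {
    sets <- stage("read_gmt", function() read_gmt(config$gene_sets))
    scores <- stage("pathway_scores", function()
      pathway_score_matrix(expr, sets))
    write_scores(scores, file.path(config$out_dir, "pathway_scores.tsv"),
                 id_col = "pathway")
    pa <- stage("pathway_association", function()
      feature_association(scores, outcome, cov))
    write_assoc(pa, file.path(config$out_dir, "pathway_association.tsv"))
    summary_list$n_pathways <- nrow(scores)
    summary_list$n_pathways_q05 <- sum(pa$q_value < 0.05, na.rm = TRUE)
  }

  ga <- stage("gene_association", function()
    feature_association(expr, outcome, cov))
  write_assoc(ga, file.path(config$out_dir, "gene_association.tsv"))
  de <- call_de_genes(ga, config$q_threshold)
  writeLines(de$up_group1, file.path(config$out_dir, "de_up_group1.txt"))
  writeLines(de$up_group0, file.path(config$out_dir, "de_up_group0.txt"))
  summary_list$n_de <- length(de$up_group1) + length(de$up_group0)
  summary_list$n_de_up_group1 <- length(de$up_group1)

  if (!is.null(config$drug_models)) {
    models <- stage("read_drug_models", function()
      read_drug_models(config$drug_models))
    drs <- stage("drs", function() drs_matrix(expr, models))
    write_scores(drs, file.path(config$out_dir, "drs.tsv"), id_col = "drug")
    da <- stage("drs_comparison", function() compare_drs(drs, outcome, cov))
    write_assoc(da, file.path(config$out_dir, "drs_association.tsv"))
    summary_list$n_drugs <- nrow(drs)
  }

  if (!is.null(config$panel)) {
    panel <- stage("read_panel", function() read_panel(config$panel))
    panel <- intersect(panel, rownames(expr))
    cc <- stage("immune_clustering", function()
      consensus_cluster(expr[panel, , drop = FALSE], seed = config$seed))
    write_scores(cc$consensus, file.path(config$out_dir, "consensus.tsv"),
                 id_col = "sample")
    utils::write.csv(
      data.frame(sample_id = names(cc$labels), cluster = cc$labels),
      file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
    flags <- derive_adverse_pathology(clinical)
    enr <- cluster_enrichment(cc$labels, flags[names(cc$labels)])
    utils::write.csv(enr, file.path(config$out_dir, "cluster_enrichment.csv"),
                     row.names = FALSE)
    summary_list$consensus_k <- cc$k
    summary_list$cluster_sizes <- as.list(table(cc$labels))
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("txcohort")),
    r_version = R.version.string,
    seed = config$seed,
    q_threshold = config$q_threshold,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    input_md5 = as.list(tools::md5sum(unlist(
      config[c("expression", "clinical", "gene_sets", "signatures",
               "drug_models", "panel")], use.names = FALSE))))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary_list, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
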