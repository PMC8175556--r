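#' Delta-Ct quantification against a housekeeping panel
#'
#' For each sample: dCt = Ct(target) - mean(Ct of housekeeping assays), and
#' relative expression 2^(-dCt). Housekeeping Ct values are aggregated by
#' arithmetic mean (equivalent to a geometric mean of the linear
#' quantities). No amplification-efficiency correction is applied. A sample
#' missing the target assay is omitted with a warning; a sample with no
#' housekeeping assay is an error.
#'
#' @param ct long-format data frame with columns sample, assay, ct,
#'   is_housekeeping (logical).
#' @param target assay id to quantify.
#' @return data frame: sample, delta_ct, rel_expr.
#' @export
delta_ct <- function(ct, target) {
  need <- c("sample", "assay", "ct", "is_housekeeping")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct) | ct$ct <= 0))
    stop("Ct values must be finite and positive")
  if (!target %in% ct$assay[!ct$is_housekeeping])
    stop("target assay not present: ", target)
  samples <- unique(ct$sample)
  rows <- lapply(samples, function(s) {
    sub <- ct[ct$sample == s, ]
    hk <- sub$ct[sub$is_housekeeping]
    if (length(hk) == 0L)
      stop("sample ", s, " has no housekeeping Ct")
    tg <- sub$ct[sub$assay == target & !sub$is_housekeeping]
    if (length(tg) == 0L) {
      warning("sample ", s, " missing target Ct; omitted")
      return(NULL)
    }
    d <- mean(tg) - mean(hk)
    data.frame(sample = s, delta_ct = d, rel_expr = 2^(-d))
  })
  do.call(rbind, rows)
}

#' Compare relative expression between groups
#'
#' Two-sided Mann-Whitney U test on per-sample relative expression plus the
#' fold difference of group medians (group 1 over group 0).
#'
#' @param rel_expr numeric per-sample relative expression.
#' @param groups binary labels per sample (1 = group of interest).
#' @return list with \code{test} (a \code{txc_test}) and
#'   \code{fold_difference}.
#' @export
group_compare_dct <- function(rel_expr, groups) {
  groups <- as.numeric(groups)
  x <- rel_expr[groups == 1]; y <- rel_expr[groups == 0]
  t <- mann_whitney_u(x, y)
  list(test = t,
       fold_difference = stats::median(x) / stats::median(y))
}
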