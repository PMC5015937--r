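#' Filter and impute a biallelic marker matrix
#'
#' Applies the marker quality-control cascade used before building the genomic
#' relationship matrix. Markers are coded -1 (homozygous minor), 0
#' (heterozygous) and 1 (homozygous major), with `NA` for missing calls.
#' Filters are applied in this order:
#' \enumerate{
#'   \item drop markers with more than 80\% missing calls or more than 20\%
#'     heterozygous calls (fraction of 0 codes among non-missing calls);
#'   \item drop lines with more than 80\% missing calls;
#'   \item subset to `keep_ids`;
#'   \item on the subset, drop markers with minor allele frequency below 0.01
#'     or more than 80\% missing;
#'   \item impute each remaining missing call with its marker mean.
#' }
#' Allele frequencies are computed from non-missing calls before imputation,
#' so an imputed call equals 2p - 1 for allele frequency p.
#'
#' @param calls numeric matrix, lines x markers, rownames are line IDs.
#' @param keep_ids line IDs to retain (default: all lines).
#' @param max_missing,max_het,min_maf filter thresholds (strict inequalities).
#' @return list with `markers` (filtered, imputed matrix) and `report`
#'   (named list of counts dropped per rule).
#' @export
filter_and_impute_markers <- function(calls, keep_ids = rownames(calls),
                                      max_missing = 0.8, max_het = 0.2,
                                      min_maf = 0.01) {
  if (is.null(rownames(calls))) stopf("marker matrix must have line IDs as rownames")
  if (anyDuplicated(rownames(calls))) stopf("duplicate line IDs in marker matrix")
  bad <- setdiff(keep_ids, rownames(calls))
  if (length(bad) > 0L)
    stopf("keep_ids not present in marker matrix: %s", paste(head(bad, 5L), collapse = ", "))
  ok_codes <- calls %in% c(-1, 0, 1) | is.na(calls)
  if (!all(ok_codes)) stopf("marker calls must be coded -1/0/1/NA")

  report <- list(n_markers_in = ncol(calls), n_lines_in = nrow(calls))

  miss_frac <- colMeans(is.na(calls))
  het_frac <- colMeans(calls == 0, na.rm = TRUE)
  het_frac[is.nan(het_frac)] <- 1   # all-missing marker: caught by miss rule anyway
  drop1 <- miss_frac > max_missing | het_frac > max_het
  report$markers_dropped_missing_or_het <- sum(drop1)
  calls <- calls[, !drop1, drop = FALSE]

  line_miss <- rowMeans(is.na(calls))
  drop_lines <- line_miss > max_missing
  report$lines_dropped_missing <- sum(drop_lines)
  calls <- calls[!drop_lines, , drop = FALSE]

  keep_ids <- intersect(keep_ids, rownames(calls))
  calls <- calls[keep_ids, , drop = FALSE]
  report$n_lines_out <- nrow(calls)

  p <- (colMeans(calls, na.rm = TRUE) + 1) / 2
  maf <- pmin(p, 1 - p)
  miss2 <- colMeans(is.na(calls))
  drop2 <- is.nan(p) | maf < min_maf | miss2 > max_missing
  report$markers_dropped_maf_or_missing_subset <- sum(drop2)
  calls <- calls[, !drop2, drop = FALSE]
  report$n_markers_out <- ncol(calls)

  if (ncol(calls) == 0L) stopf("no markers survive QC")

  # mean imputation, frequency-consistent with p computed pre-imputation
  if (anyNA(calls)) {
    mns <- colMeans(calls, na.rm = TRUE)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- mns[idx[, 2L]]
  }
  list(markers = calls, report = report)
}

#' Genomic relationship matrix from imputed markers
#'
#' VanRaden's allele-frequency-scaled cross product. With p_j the frequency
#' of the allele coded +1 at marker j (p_j = (mean_j + 1)/2 on the -1/0/1
#' scale) and Z the column-centered call matrix,
#' \deqn{G = Z Z' / (2 \sum_j p_j (1 - p_j)).}
#'
#' @param markers imputed marker matrix (no missing calls), lines x markers.
#' @return symmetric PSD relationship matrix with line IDs as dimnames and
#'   attribute `kind = "G"`.
#' @export
genomic_relationship <- function(markers) {
  if (anyNA(markers)) stopf("markers must be imputed (no missing calls)")
  if (is.null(rownames(markers))) stopf("marker matrix must have line IDs as rownames")
  p <- (colMeans(markers) + 1) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stopf("all markers monomorphic: G denominator is zero")
  Z <- sweep(markers, 2L, colMeans(markers))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(markers), rownames(markers))
  attr(G, "kind") <- "G"
  G
}
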