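#' Read and validate a plot-level phenotype table
#'
#' Long-format CSV with required columns `line`, `environment`, `trial`,
#' `replicate`, `block`, `trait`, `value` and optional `date`, `lodging`,
#' `dthd`. Comment lines starting with `#` are skipped. The joint key
#' (environment, trial, replicate, block, line, trait, date) must be unique.
#'
#' @param path CSV file path.
#' @return validated plot table data frame.
#' @export
read_plot_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_plot_table(d)
}

#' @rdname read_plot_table
#' @param plots plot table to validate.
#' @export
validate_plot_table <- function(plots) {
  need <- c("line", "environment", "trial", "replicate", "block", "trait",
            "value")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0L)
    stopf("plot table missing required column(s): %s", paste(miss, collapse = ", "))
  if (!"date" %in% names(plots)) plots$date <- NA_character_
  key <- paste(plots$environment, plots$trial, plots$replicate, plots$block,
               plots$line, plots$trait, plots$date, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stopf("duplicate plot records at rows: %s",
          paste(head(dup, 5L), collapse = ", "))
  }
  if (any(is.infinite(plots$value), na.rm = TRUE))
    stopf("plot values must be finite or missing")
  plots
}

#' Write a table as CSV with a provenance header
#'
#' Prepends `#`-prefixed comment lines carrying a configuration hash and
#' seed so that outputs are traceable; the package readers skip them.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed seed to record, or `NULL`.
#' @param config object whose serialized hash is recorded, or `NULL`.
#' @export
write_table_csv <- function(x, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  # small stable polynomial hash (provenance tag, not cryptographic)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Read a marker matrix
#'
#' CSV/TSV with the first column holding line IDs and remaining columns
#' markers coded -1/0/1/NA.
#'
#' @param path file path.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @return numeric matrix with line rownames.
#' @export
read_markers <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE,
                check.names = FALSE)
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stopf("duplicate line IDs in marker file")
  M <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  bad <- !(M %in% c(-1, 0, 1) | is.na(M))
  if (any(bad)) stopf("marker calls must be coded -1/0/1/NA")
  M
}

#' @rdname read_markers
#' @param markers marker matrix to write.
#' @export
write_markers <- function(markers, path, sep = ",") {
  d <- data.frame(line = rownames(markers), markers, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' CSV with columns `line`, `parent1`, `parent2`; empty cells mark unknown
#' parents. Acyclicity is enforced.
#'
#' @param path file path.
#' @return pedigree data frame.
#' @export
read_pedigree <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                na.strings = c("NA", ""))
  need <- c("line", "parent1", "parent2")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stopf("pedigree missing column(s): %s", paste(miss, collapse = ", "))
  parents <- setdiff(na.omit(c(d$parent1, d$parent2)), d$line)
  full <- if (length(parents))
    rbind(d[need], data.frame(line = parents, parent1 = NA_character_,
                              parent2 = NA_character_))
  else d[need]
  pedigree_topo_order(full)   # errors on cycles, listing the lines involved
  d
}

#' Read a square relationship matrix
#'
#' CSV whose first row and first column carry line IDs; symmetry is checked
#' within tolerance and the matrix is symmetrized.
#'
#' @param path file path.
#' @param tol symmetry tolerance.
#' @return relationship matrix.
#' @export
read_relationship_matrix <- function(path, tol = 1e-8) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                check.names = FALSE)
  ids <- as.character(d[[1L]])
  K <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  dimnames(K) <- list(ids, colnames(d)[-1L])
  if (!identical(rownames(K), colnames(K)))
    stopf("relationship matrix row and column IDs differ")
  if (max(abs(K - t(K))) > tol)
    stopf("relationship matrix asymmetric beyond tolerance")
  K <- (K + t(K)) / 2
  check_relationship(K, tol = tol)
  K
}

#' @rdname read_relationship_matrix
#' @param K relationship matrix to write.
#' @export
write_relationship_matrix <- function(K, path) {
  d <- data.frame(line = rownames(K), K, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
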