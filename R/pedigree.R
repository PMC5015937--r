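#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method: lines are processed parents-first; for line x with parents
#' p1 and p2, A_xj = 0.5 (A_{j,p1} + A_{j,p2}) for every previously processed
#' line j (terms for unknown parents are zero), and
#' A_xx = 1 + 0.5 A_{p1,p2} (zero if either parent is unknown). The result
#' equals twice the coefficient of parentage; diagonals are 1 + F with F the
#' inbreeding coefficient.
#'
#' @param ped data frame with columns `line`, `parent1`, `parent2`; `NA` or
#'   `""` marks an unknown parent. Parents without their own record are
#'   treated as non-inbred founders.
#' @param ids line IDs for the returned submatrix (default: all pedigree
#'   lines, pedigree order).
#' @return symmetric relationship matrix over `ids` with attribute
#'   `kind = "A"`.
#' @export
pedigree_relationship <- function(ped, ids = NULL) {
  ped <- as.data.frame(ped)
  need <- c("line", "parent1", "parent2")
  if (!all(need %in% names(ped)))
    stopf("pedigree must have columns line, parent1, parent2")
  for (cc in need) {
    ped[[cc]] <- as.character(ped[[cc]])
    ped[[cc]][!is.na(ped[[cc]]) & ped[[cc]] == ""] <- NA_character_
  }
  if (anyNA(ped$line)) stopf("pedigree contains records with missing line ID")
  if (anyDuplicated(ped$line)) stopf("duplicate line IDs in pedigree")

  parents <- setdiff(na.omit(c(ped$parent1, ped$parent2)), ped$line)
  if (length(parents) > 0L)
    ped <- rbind(ped[need],
                 data.frame(line = parents, parent1 = NA_character_,
                            parent2 = NA_character_))
  if (is.null(ids)) ids <- ped$line
  missing_ids <- setdiff(ids, ped$line)
  if (length(missing_ids) > 0L)
    stopf("ids absent from pedigree closure: %s",
          paste(head(missing_ids, 5L), collapse = ", "))

  order_ids <- pedigree_topo_order(ped)
  n <- length(order_ids)
  pos <- setNames(seq_len(n), order_ids)
  p1 <- pos[ped$parent1[match(order_ids, ped$line)]]
  p2 <- pos[ped$parent2[match(order_ids, ped$line)]]

  A <- matrix(0, n, n, dimnames = list(order_ids, order_ids))
  for (x in seq_len(n)) {
    a1 <- p1[x]; a2 <- p2[x]
    if (x > 1L) {
      j <- seq_len(x - 1L)
      rel <- numeric(x - 1L)
      if (!is.na(a1)) rel <- rel + 0.5 * A[j, a1]
      if (!is.na(a2)) rel <- rel + 0.5 * A[j, a2]
      A[j, x] <- rel
      A[x, j] <- rel
    }
    A[x, x] <- 1 + if (!is.na(a1) && !is.na(a2)) 0.5 * A[a1, a2] else 0
  }
  A <- A[ids, ids, drop = FALSE]
  attr(A, "kind") <- "A"
  A
}

# Topological order of pedigree lines (parents before offspring), by Kahn's
# algorithm. Errors listing the lines involved when a cycle is present.
pedigree_topo_order <- function(ped) {
  id <- ped$line
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  par <- cbind(unname(idx[ped$parent1]), unname(idx[ped$parent2]))
  npar <- rowSums(!is.na(par))
  # children lists
  kids <- vector("list", n)
  for (x in seq_len(n)) for (p in par[x, ]) if (!is.na(p))
    kids[[p]] <- c(kids[[p]], x)
  queue <- which(npar == 0L)
  out <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids[[v]]) {
      npar[w] <- npar[w] - 1L
      if (npar[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    left <- id[setdiff(seq_len(n), out)]
    stopf("pedigree cycle detected among: %s", paste(left, collapse = ", "))
  }
  id[out]
}
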