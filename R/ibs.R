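#' Pairwise identity-by-state similarity
#'
#' For a pair of samples, IBS is (number of markers sharing two alleles +
#' 0.5 x number sharing one allele) / number of markers jointly called: with
#' dosages a and b at a marker the shared-allele count is `2 - |a - b|`, and
#' markers where either call is missing are excluded from numerator and
#' denominator. Values lie between 0 and 1 with 1 on the diagonal.
#'
#' @param g a [geno()] object (normally post-QC).
#' @return An object of class `ibs_matrix`: a list with `samples`, `ibs`
#'   (symmetric similarity matrix, `NA` where a pair shares no called
#'   markers) and `n_used` (markers used per pair).
#' @export
ibs_matrix <- function(g) {
  stopifnot(inherits(g, "geno"))
  cl <- g$calls
  g0 <- (!is.na(cl) & cl == 0L) + 0
  g1 <- (!is.na(cl) & cl == 1L) + 0
  g2 <- (!is.na(cl) & cl == 2L) + 0
  called <- g0 + g1 + g2

  same <- tcrossprod(g0) + tcrossprod(g1) + tcrossprod(g2)
  one_apart <- tcrossprod(g0, g1) + tcrossprod(g1, g0) +
    tcrossprod(g1, g2) + tcrossprod(g2, g1)
  n_used <- tcrossprod(called)

  ibs <- (2 * same + one_apart) / (2 * n_used)
  ibs[n_used == 0] <- NA_real_
  diag(ibs)[diag(n_used) > 0] <- 1
  dimnames(ibs) <- dimnames(n_used) <- list(g$samples, g$samples)
  structure(list(samples = g$samples, ibs = ibs,
                 n_used = matrix(as.integer(n_used), nrow(n_used),
                                 dimnames = dimnames(n_used))),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  off <- x$ibs[upper.tri(x$ibs)]
  cat(sprintf("<ibs_matrix> %d samples; off-diagonal IBS %.3f-%.3f (median %.3f)\n",
              length(x$samples), min(off, na.rm = TRUE), max(off, na.rm = TRUE),
              stats::median(off, na.rm = TRUE)))
  invisible(x)
}

#' Long-format view of an IBS matrix
#'
#' @param ibs an [ibs_matrix()].
#' @return A tibble `id1`, `id2`, `ibs`, `n_markers` over unordered pairs.
#' @export
ibs_pairs <- function(ibs) {
  ut <- upper.tri(ibs$ibs)
  idx <- which(ut, arr.ind = TRUE)
  vals <- ibs$ibs[ut]
  n_used <- ibs$n_used[ut]
  tibble::tibble(
    id1 = ibs$samples[idx[, 1]],
    id2 = ibs$samples[idx[, 2]],
    ibs = vals,
    n_markers = n_used
  )
}
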