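#' Principal components of the standardized relationship matrix
#'
#' Each genotype column j is standardized to `(call - 2*p_j) / sqrt(p_j *
#' (1 - p_j))` with `p_j` the observed allele-b frequency; missing calls are
#' imputed to the column mean (zero after centering). The relationship matrix
#' is `(1/L) * S %*% t(S)` over the L markers and its top-k eigenpairs are
#' returned; per-sample scores are the eigenvectors scaled by the square root
#' of their eigenvalues, so score geometry reflects variance along each axis.
#'
#' @param g a [geno()] object; markers must be polymorphic (post-QC).
#' @param k number of components, `k < n_samples`.
#' @return An object of class `grm_pca`: list with `eigenvalues` (length k,
#'   descending), `scores` (tibble: `id`, `PC1..PCk`), `grm` (the n x n
#'   relationship matrix) and `n_markers`.
#' @export
pca_standardized_grm <- function(g, k = 10) {
  stopifnot(inherits(g, "geno"))
  n <- n_samples(g)
  if (k >= n) {
    stop("k must be smaller than the number of samples")
  }
  af <- allele_freq(g)
  if (any(is.na(af$q) | af$q <= 0 | af$q >= 1)) {
    bad <- af$name[is.na(af$q) | af$q <= 0 | af$q >= 1]
    stop("zero-variance (monomorphic or uncalled) marker(s) in PCA input: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  L <- n_markers(g)
  s <- sweep(g$calls, 2, 2 * af$q, `-`)
  s <- sweep(s, 2, sqrt(af$q * (1 - af$q)), `/`)
  s[is.na(s)] <- 0  # mean imputation after centering
  grm <- tcrossprod(s) / L
  dimnames(grm) <- list(g$samples, g$samples)

  eig <- eigen(grm, symmetric = TRUE)
  vals <- eig$values[seq_len(k)]
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(vecs, 2, sqrt(pmax(vals, 0)), `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    eigenvalues = vals,
    scores = dplyr::bind_cols(tibble::tibble(id = g$samples),
                              tibble::as_tibble(scores)),
    grm = grm,
    n_markers = L
  ), class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("<grm_pca> %d samples, %d markers, %d components\n",
              nrow(x$scores), x$n_markers, length(x$eigenvalues)))
  cat("  eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = " "),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.grm_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    prop_trace = x$eigenvalues / sum(diag(x$grm))
  )
}

#' Plot PCA scores
#'
#' @param object a [pca_standardized_grm()] result.
#' @param components which two components to draw.
#' @param breeds optional data frame `id`, `breed` for colouring.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.grm_pca <- function(object, components = c(1, 2), breeds = NULL, ...) {
  xc <- paste0("PC", components[1])
  yc <- paste0("PC", components[2])
  df <- object$scores
  if (!is.null(breeds)) {
    df <- dplyr::left_join(df, breeds[, c("id", "breed")], by = "id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xc]], .data[[yc]],
                                          colour = .data$breed))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xc]], .data[[yc]]))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (eigenvalue %.2f)", xc, object$eigenvalues[components[1]]),
      y = sprintf("%s (eigenvalue %.2f)", yc, object$eigenvalues[components[2]])
    ) +
    ggplot2::theme_minimal()
}
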