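#' Pairwise Weir-Cockerham Fst between breeds
#'
#' For every pair of breeds, the Weir-Cockerham (1984) theta estimator for
#' two populations at biallelic loci, combined over loci as a ratio of sums:
#' `theta = sum_j a_j / sum_j (a_j + b_j + c_j)` with the among-population
#' (a), among-individual (b) and within-individual (c) variance components.
#' Negative per-locus components are kept, so a pair of undifferentiated
#' populations can yield a slightly negative theta. Loci where either breed
#' has fewer than two genotyped samples, or that are monomorphic across the
#' pair, are excluded from the sums.
#'
#' @param g a [geno()] object.
#' @param sample_breeds data frame with columns `id`, `breed`.
#' @return An object of class `fst_matrix`: list with `breeds`, `fst`
#'   (symmetric matrix, zero diagonal, `NA` where no usable loci) and
#'   `pairs` (long tibble `breed1`, `breed2`, `fst`, `n_loci`).
#' @export
pairwise_fst <- function(g, sample_breeds) {
  stopifnot(inherits(g, "geno"))
  breeds <- sample_breeds$breed[match(g$samples, sample_breeds$id)]
  if (anyNA(breeds)) {
    stop("breed missing for sample(s): ",
         paste(utils::head(g$samples[is.na(breeds)], 5), collapse = ", "))
  }
  labels <- sort(unique(breeds))
  k <- length(labels)
  stats <- lapply(labels, function(b) breed_locus_stats(g, breeds == b))

  m <- matrix(0, k, k, dimnames = list(labels, labels))
  pairs <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        est <- wc_theta_pair(stats[[i]], stats[[j]])
        m[i, j] <- m[j, i] <- est$theta
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          breed1 = labels[i], breed2 = labels[j],
          fst = est$theta, n_loci = est$n_loci
        )
      }
    }
  }
  structure(list(breeds = labels, fst = m,
                 pairs = dplyr::bind_rows(pairs)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("<fst_matrix> %d breeds\n", length(x$breeds)))
  if (nrow(x$pairs) > 0) {
    rng <- range(x$pairs$fst, na.rm = TRUE)
    cat(sprintf("  pairwise theta range: %.3f to %.3f\n", rng[1], rng[2]))
  }
  invisible(x)
}

# Per-locus sample size, allele-b frequency and observed het proportion for
# the samples flagged in `mask`.
breed_locus_stats <- function(g, mask) {
  cl <- g$calls[mask, , drop = FALSE]
  n <- colSums(!is.na(cl))
  q <- ifelse(n > 0, colSums(cl, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(cl == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = q, h = h)
}

# Weir-Cockerham (1984) two-population theta, ratio of sums over loci.
wc_theta_pair <- function(s1, s2) {
  ok <- s1$n >= 2 & s2$n >= 2
  n1 <- s1$n[ok]; n2 <- s2$n[ok]
  p1 <- s1$p[ok]; p2 <- s2$p[ok]
  h1 <- s1$h[ok]; h2 <- s2$h[ok]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2

  # monomorphic-across-pair loci carry no information (0/0); drop them
  poly <- pbar > 0 & pbar < 1
  num <- sum(a[poly])
  den <- sum((a + b + c)[poly])
  list(theta = if (sum(poly) == 0 || den == 0) NA_real_ else num / den,
       n_loci = sum(poly))
}
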