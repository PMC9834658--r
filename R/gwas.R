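#' IBS kinship matrix for the mixed model
#'
#' Uses the pairwise IBS similarity matrix as the relationship matrix of the
#' random polygenic effect, floored to positive semi-definiteness: negative
#' eigenvalues (numerically tiny for IBS matrices) are set to zero and the
#' matrix reconstructed.
#'
#' @param ibs an [ibs_matrix()] with no missing pairs on the GWAS samples.
#' @return A symmetric PSD matrix with sample ids as dimnames.
#' @export
kinship_ibs <- function(ibs) {
  m <- ibs$ibs
  if (anyNA(m)) {
    stop("IBS matrix has missing pairs; kinship requires complete IBS")
  }
  eig <- eigen(m, symmetric = TRUE)
  if (min(eig$values) < 0) {
    vals <- pmax(eig$values, 0)
    m <- eig$vectors %*% (vals * t(eig$vectors))
    m <- (m + t(m)) / 2
    dimnames(m) <- list(ibs$samples, ibs$samples)
  }
  m
}

#' Dosage matrix with mean imputation
#'
#' @param g a [geno()] object.
#' @return Numeric samples x markers matrix; missing calls replaced by the
#'   marker mean dosage.
#' @export
dosage_matrix <- function(g) {
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    x[idx] <- mu[idx[, 2]]
  }
  x
}

#' Fixed-effects design from birth covariates
#'
#' Birth date is reduced to birth year (finer resolution is unidentifiable
#' with cohort-level effects) and both birth year and birth place enter as
#' categorical factors.
#'
#' @param samples data frame with columns `id`, `birth_date`, `birth_place`.
#' @param ids sample ids, in the order of the response vector.
#' @return A design matrix with intercept and treatment-coded dummies.
#' @export
covariate_design <- function(samples, ids) {
  rows <- match(ids, samples$id)
  if (anyNA(rows)) {
    stop("covariates missing for sample(s): ",
         paste(utils::head(ids[is.na(rows)], 5), collapse = ", "))
  }
  year <- sub("^([0-9]{4}).*$", "\\1", as.character(samples$birth_date[rows]))
  df <- data.frame(
    birth_year = factor(year),
    birth_place = factor(as.character(samples$birth_place[rows]))
  )
  df <- df[, vapply(df, function(f) nlevels(f) > 1, logical(1)), drop = FALSE]
  if (ncol(df) == 0) {
    return(matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(~ ., df)
}

#' EMMA-style REML variance components
#'
#' Restricted maximum likelihood for the model `y = X0 b + u + e`,
#' `u ~ N(0, vg K)`, `e ~ N(0, ve I)`, via a single spectral decomposition
#' and a one-dimensional optimization over `delta = ve/vg`: the restricted
#' likelihood is profiled on the nonzero eigenvalues of `S (K + I) S` (S the
#' projection orthogonal to X0), evaluated on a 100-point log-spaced delta
#' grid and refined by local optimization around the grid optimum.
#'
#' @param y numeric response.
#' @param X0 fixed-effects design (intercept + covariates), no markers.
#' @param K PSD kinship matrix.
#' @param delta_range log10 search range for `ve/vg`. Default `c(-5, 5)`.
#' @return A list with `vg`, `ve`, `delta`, `loglik` (restricted), `h2`
#'   (`vg/(vg+ve)`), and the spectral pieces reused by the scan (`eigvals`,
#'   `eigvecs` of K).
#' @export
reml_variance_components <- function(y, X0, K, delta_range = c(-5, 5)) {
  y <- as.numeric(y)
  n <- length(y)
  X0 <- as.matrix(X0)
  stopifnot(nrow(X0) == n, nrow(K) == n)
  if (stats::var(y) == 0) {
    stop("response is constant; variance components are undefined")
  }
  qr0 <- qr(X0)
  q <- qr0$rank
  if (n < q + 2) {
    stop("too few observations for the fixed-effects design")
  }
  # S (K + I) S, spectrum shifted by +1 for conditioning
  SKS <- qr.resid(qr0, t(qr.resid(qr0, K + diag(n))))
  SKS <- (SKS + t(SKS)) / 2
  eig <- eigen(SKS, symmetric = TRUE)
  lambda <- pmax(eig$values[seq_len(n - q)] - 1, 0)
  eta <- as.numeric(crossprod(eig$vectors[, seq_len(n - q), drop = FALSE], y))
  eta2 <- eta^2

  ll <- function(log10_delta) {
    delta <- 10^log10_delta
    denom <- lambda + delta
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(sum(eta2 / denom))) -
             sum(log(denom)))
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = 100)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  best <- if (opt$objective >= vals[i]) opt$maximum else grid[i]

  delta <- 10^best
  vg <- sum(eta2 / (lambda + delta)) / (n - q)
  ve <- delta * vg
  eigK <- eigen(K, symmetric = TRUE)
  list(vg = vg, ve = ve, delta = delta, loglik = ll(best),
       h2 = vg / (vg + ve),
       eigvals = pmax(eigK$values, 0), eigvecs = eigK$vectors)
}

# Rotate the model by V^{-1/2} using the spectral decomposition of K and
# fixed variance components, then residualize against the base design.
rotate_model <- function(y, X0, vc) {
  d <- 1 / sqrt(vc$vg * vc$eigvals + vc$ve)
  Ut <- t(vc$eigvecs)
  list(
    d = d, Ut = Ut,
    yr = d * as.numeric(Ut %*% y),
    X0r = d * (Ut %*% X0)
  )
}

#' Single-marker mixed-model scan
#'
#' Tests every marker, one at a time, as a fixed effect in the rotated model
#' with variance components held fixed (population-parameters-previously-
#' determined approximation): generalized least squares via the spectral
#' rotation, Wald t-test on the allele-substitution coefficient. Dosages are
#' the count of the minor allele, so the reported effect is per copy of the
#' minor allele. Markers monomorphic in the sample or collinear with the
#' covariates yield `NA` statistics.
#'
#' @param y numeric response (daily gain).
#' @param X0 base fixed-effects design (see [covariate_design()]).
#' @param K kinship matrix (see [kinship_ibs()]).
#' @param g a [geno()] object aligned with `y`.
#' @param vc variance components from [reml_variance_components()]; computed
#'   internally when `NULL`.
#' @param exclude marker names to leave out (cofactors).
#' @return A tibble: `marker`, `chromosome`, `position_bp`, `ase`, `se`,
#'   `t`, `p`, `neg_log10_p`, `fdr_q`, `cofactor` (all `FALSE` here).
#' @export
single_marker_scan <- function(y, X0, K, g, vc = NULL, exclude = character()) {
  stopifnot(inherits(g, "geno"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == n_samples(g))
  if (is.null(vc)) {
    vc <- reml_variance_components(y, X0, K)
  }
  rot <- rotate_model(y, X0, vc)
  keep <- !(g$markers$name %in% exclude)
  G <- dosage_matrix(geno_subset(g, markers = which(keep)))
  Gr <- rot$d * (rot$Ut %*% G)

  qr0 <- qr(rot$X0r)
  q <- qr0$rank
  ry <- qr.resid(qr0, rot$yr)
  RG <- qr.resid(qr0, Gr)
  sxx <- colSums(RG^2)
  total <- colSums(Gr^2)
  usable <- sxx > 1e-10 * pmax(total, 1)
  df <- n - q - 1

  beta <- se <- tval <- p <- rep(NA_real_, ncol(G))
  sxy <- colSums(RG * ry)
  syy <- sum(ry^2)
  beta[usable] <- sxy[usable] / sxx[usable]
  rss <- syy - beta[usable] * sxy[usable]
  sigma2 <- pmax(rss, 0) / df
  se[usable] <- sqrt(sigma2 / sxx[usable])
  tval[usable] <- beta[usable] / se[usable]
  p[usable] <- 2 * stats::pt(-abs(tval[usable]), df)

  mk <- g$markers[keep, ]
  tibble::tibble(
    marker = mk$name,
    chromosome = mk$chromosome,
    position_bp = mk$position_bp,
    ase = beta,
    se = se,
    t = tval,
    p = p,
    neg_log10_p = -log10(p),
    fdr_q = bh_fdr(p),
    cofactor = FALSE
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, `q_i = min_{j>=i} m p_(j) / j`
#' capped at 1, mapped back to input order. `NA` p-values stay `NA` and do
#' not count toward `m`.
#'
#' @param p numeric vector of p-values between 0 and 1.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  stats::p.adjust(p, method = "BH")
}

#' Multi-locus mixed-model scan with forward cofactor selection
#'
#' Forward stage: at each step the full genome is scanned
#' ([single_marker_scan()]) with the current cofactors in the fixed effects
#' and variance components re-estimated for that design; the most significant
#' candidate (smallest p, ties by marker name) enters as a cofactor while its
#' Benjamini-Hochberg q-value is below `alpha`, up to `max_cofactors`.
#' Backward stage: cofactors non-significant (Wald p >= `alpha`) in the final
#' joint model are pruned, worst first. Reported statistics: each surviving
#' cofactor keeps the statistics from the scan at which it entered;
#' non-cofactors come from one final scan under the final cofactor set, and
#' the FDR column is recomputed across the full reported table.
#'
#' @inheritParams single_marker_scan
#' @param max_cofactors maximum number of markers promoted to fixed effects.
#' @param alpha entry/exit significance level on the FDR (entry) and Wald p
#'   (exit) scale. Default 0.05.
#' @return An object of class `mlmm_fit`: list with `results` (tibble as in
#'   [single_marker_scan()], `cofactor` flagging selected markers),
#'   `cofactors`, `vc` (final variance components), `steps` (per-step log
#'   tibble), `n`.
#' @export
mlmm_stepwise <- function(y, X0, K, g, max_cofactors = 10, alpha = 0.05) {
  y <- as.numeric(y)
  cofactors <- character(0)
  entry_rows <- list()
  steps <- list()

  design_with <- function(cof) {
    if (length(cof) == 0) {
      return(X0)
    }
    cbind(X0, dosage_matrix(geno_subset(g, markers = cof)))
  }

  repeat {
    X <- design_with(cofactors)
    vc <- reml_variance_components(y, X, K)
    scan <- single_marker_scan(y, X, K, g, vc = vc, exclude = cofactors)
    ok <- !is.na(scan$p)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1L, n_cofactors = length(cofactors),
      vg = vc$vg, ve = vc$ve,
      best_marker = if (any(ok)) scan$marker[which.min(scan$p)] else NA_character_,
      best_q = if (any(ok)) min(scan$fdr_q, na.rm = TRUE) else NA_real_
    )
    if (!any(ok)) break
    best <- which(ok)[order(scan$p[ok], scan$marker[ok])][1]
    if (scan$fdr_q[best] >= alpha || length(cofactors) >= max_cofactors) break
    entry_rows[[scan$marker[best]]] <- scan[best, ]
    cofactors <- c(cofactors, scan$marker[best])
  }

  # backward pruning on joint Wald tests in the final model
  while (length(cofactors) > 0) {
    X <- design_with(cofactors)
    vc <- reml_variance_components(y, X, K)
    wald <- joint_wald(y, X, K, vc, n_base = ncol(X0))
    if (all(wald < alpha, na.rm = TRUE)) break
    worst <- which.max(wald)
    cofactors <- cofactors[-worst]
  }
  entry_rows <- entry_rows[cofactors]

  X <- design_with(cofactors)
  vc <- reml_variance_components(y, X, K)
  final_scan <- single_marker_scan(y, X, K, g, vc = vc, exclude = cofactors)
  results <- final_scan
  if (length(cofactors) > 0) {
    cof_tbl <- dplyr::bind_rows(entry_rows)
    cof_tbl$cofactor <- TRUE
    results <- dplyr::bind_rows(cof_tbl, final_scan)
  }
  results$fdr_q <- bh_fdr(results$p)
  results <- results[match(g$markers$name, results$marker), ]
  results <- results[!is.na(results$marker), ]

  structure(list(
    results = results,
    cofactors = cofactors,
    vc = vc,
    steps = dplyr::bind_rows(steps),
    n = length(y)
  ), class = "mlmm_fit")
}

# Wald p-values for the cofactor columns (those beyond the first n_base) of
# the rotated joint model.
joint_wald <- function(y, X, K, vc, n_base) {
  rot <- rotate_model(y, X, vc)
  fit <- stats::lm.fit(rot$X0r, rot$yr)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  xtxi <- chol2inv(chol(crossprod(rot$X0r)))
  se <- sqrt(diag(xtxi) * rss / df)
  tv <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tv), df)
  p[seq(n_base + 1, ncol(X))]
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat(sprintf("<mlmm_fit> %d samples, %d markers tested, %d cofactor(s)\n",
              x$n, nrow(x$results), length(x$cofactors)))
  cat(sprintf("  variance components: vg = %.4g, ve = %.4g (h2 = %.3f)\n",
              x$vc$vg, x$vc$ve, x$vc$h2))
  if (length(x$cofactors) > 0) {
    cat("  cofactors:", paste(x$cofactors, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Broom-style accessors
#'
#' `tidy()` returns per-unit tables (markers, nodes, components); `glance()`
#' one-row model summaries.
#'
#' @param x a fitted flocknet object.
#' @param ... ignored.
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
tidy.mlmm_fit <- function(x, ...) x$results

#' @export
#' @rdname tidiers
glance.mlmm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_markers = nrow(x$results),
    n_cofactors = length(x$cofactors),
    vg = x$vc$vg, ve = x$vc$ve, h2 = x$vc$h2,
    min_p = min(x$results$p, na.rm = TRUE)
  )
}

#' Manhattan plot of an association scan
#'
#' @param object an `mlmm_fit` or a [single_marker_scan()] tibble.
#' @param fdr_line draw the largest -log10 p with `fdr_q < 0.05`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.mlmm_fit <- function(object, fdr_line = TRUE, ...) {
  df <- object$results
  df <- dplyr::arrange(df, as.numeric(.data$chromosome), .data$position_bp)
  df$index <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$neg_log10_p,
                                        colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_point(data = df[df$cofactor, ], colour = "red", size = 2) +
    ggplot2::labs(x = "marker index (by chromosome, position)",
                  y = expression(-log[10] * P)) +
    ggplot2::theme_minimal()
  if (fdr_line && any(df$fdr_q < 0.05, na.rm = TRUE)) {
    cut <- min(df$neg_log10_p[df$fdr_q < 0.05], na.rm = TRUE)
    p <- p + ggplot2::geom_hline(yintercept = cut, linetype = 2)
  }
  p
}
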