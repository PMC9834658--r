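#' Breed-level diversity: Ho, He and the inbreeding coefficient
#'
#' Observed heterozygosity per breed is the mean over markers of the fraction
#' of heterozygous calls among that breed's non-missing calls. Expected
#' heterozygosity is the mean over markers of `2*p*q`; by default the allele
#' frequencies come from the pooled panel (all samples together), so He is a
#' single panel-wide value shared by every breed, the convention under which
#' a multi-breed diversity table carries one He column. The breed inbreeding
#' coefficient is `Fis = 1 - Ho/He`, reported `NA` when He is zero.
#'
#' @param g a [geno()] object.
#' @param sample_breeds data frame with columns `id` and `breed` covering the
#'   samples of `g`.
#' @param he_frequencies `"pooled"` (default) to compute He from panel-wide
#'   allele frequencies, or `"breed"` for breed-specific frequencies.
#' @return A tibble `breed`, `n_samples`, `ho`, `he`, `fis`, ordered by
#'   `fis`.
#' @export
breed_diversity <- function(g, sample_breeds, he_frequencies = c("pooled", "breed")) {
  stopifnot(inherits(g, "geno"))
  he_frequencies <- match.arg(he_frequencies)
  breeds <- sample_breeds$breed[match(g$samples, sample_breeds$id)]
  if (anyNA(breeds)) {
    stop("breed missing for sample(s): ",
         paste(utils::head(g$samples[is.na(breeds)], 5), collapse = ", "))
  }
  af_pooled <- allele_freq(g)
  he_pooled <- mean(2 * af_pooled$p * af_pooled$q, na.rm = TRUE)

  per_breed <- lapply(sort(unique(breeds)), function(b) {
    gb <- geno_subset(g, samples = which(breeds == b))
    afb <- allele_freq(gb)
    ho <- mean(afb$het_rate, na.rm = TRUE)
    he <- if (he_frequencies == "pooled") {
      he_pooled
    } else {
      mean(2 * afb$p * afb$q, na.rm = TRUE)
    }
    tibble::tibble(breed = b, n_samples = n_samples(gb), ho = ho, he = he,
                   fis = fis_from_het(ho, he))
  })
  dplyr::arrange(dplyr::bind_rows(per_breed), .data$fis)
}

#' Inbreeding coefficient from heterozygosities
#'
#' The breed-level form `Fis = 1 - Ho/He`; `NA` when He is zero or missing.
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity.
#' @return Numeric vector of Fis values.
#' @export
fis_from_het <- function(ho, he) {
  ifelse(is.na(he) | he == 0, NA_real_, 1 - ho / he)
}

#' Individual inbreeding from homozygous-marker counts
#'
#' Per sample, `F = (observed_hom - expected_hom) / (L_used - expected_hom)`
#' where the expected number of homozygous markers is
#' `sum_j (1 - 2 p_j q_j T_j / (T_j - 1))` over the markers at which the
#' sample is genotyped, `p_j`/`q_j` are allele frequencies on the full sample
#' set, and `T_j` is twice the number of non-missing genotypes at marker j.
#' Markers with `T_j <= 2` are excluded panel-wide (the unbiased
#' heterozygosity correction `T/(T-1)` needs more than one genotype).
#'
#' @param g a [geno()] object; frequencies are computed on all its samples.
#' @return A tibble `id`, `observed_hom`, `expected_hom`, `l_used`, `f`;
#'   `f` is `NA` for a sample with no usable calls.
#' @export
individual_inbreeding <- function(g) {
  stopifnot(inherits(g, "geno"))
  af <- allele_freq(g)
  use <- !is.na(af$T) & af$T > 2L
  if (!any(use)) {
    stop("no markers with more than one non-missing genotype")
  }
  cl <- g$calls[, use, drop = FALSE]
  p <- af$p[use]
  q <- af$q[use]
  Tj <- af$T[use]
  # per-marker expected homozygosity with the finite-sample correction
  exp_hom_j <- 1 - 2 * p * q * Tj / (Tj - 1)

  called <- !is.na(cl)
  observed_hom <- rowSums(called & cl != 1L)
  expected_hom <- as.numeric(called %*% exp_hom_j)
  l_used <- rowSums(called)
  denom <- l_used - expected_hom
  f <- unname(ifelse(l_used == 0 | denom == 0, NA_real_,
                     (observed_hom - expected_hom) / denom))
  tibble::tibble(
    id = g$samples,
    observed_hom = unname(as.integer(observed_hom)),
    expected_hom = expected_hom,
    l_used = unname(as.integer(l_used)),
    f = f
  )
}
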