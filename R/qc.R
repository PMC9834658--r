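#' Marker-level quality control
#'
#' Removes, in a fixed order, (1) unmapped markers (chromosome `"0"`,
#' missing, or unplaced), (2) markers whose call rate is not strictly above
#' `call_rate_min`, and (3) markers whose minor allele frequency is not
#' strictly above `maf_min`, MAF being computed after the call-rate removal.
#' All inequalities are strict, so boundary markers (call rate exactly 0.95,
#' MAF exactly 0.05) are removed. Marker order is preserved and the filter is
#' idempotent.
#'
#' @param g a [geno()] object.
#' @param maf_min minimum minor allele frequency (exclusive). Default 0.05.
#' @param call_rate_min minimum marker call rate (exclusive). Default 0.95.
#' @return A list with `geno` (the filtered matrix) and `report` (a
#'   [qc_report()] tibble of per-rule removal counts).
#' @export
filter_markers <- function(g, maf_min = 0.05, call_rate_min = 0.95) {
  stopifnot(inherits(g, "geno"), n_markers(g) > 0)
  chrom <- g$markers$chromosome
  unmapped <- is.na(chrom) | chrom %in% c("0", "", "unplaced")
  keep1 <- !unmapped

  af1 <- allele_freq(geno_subset(g, markers = which(keep1)))
  low_cr <- !(af1$call_rate > call_rate_min)
  keep2 <- which(keep1)[!low_cr]

  af2 <- allele_freq(geno_subset(g, markers = keep2))
  low_maf <- is.na(af2$maf) | !(af2$maf > maf_min)
  keep3 <- keep2[!low_maf]

  out <- geno_subset(g, markers = keep3)
  if (n_markers(out) == 0) {
    warning("all markers removed by QC: empty marker panel")
  }
  report <- qc_report(
    axis = "marker",
    n_in = n_markers(g), n_out = n_markers(out),
    removals = c(unmapped = sum(unmapped),
                 marker_call_rate = sum(low_cr),
                 maf = sum(low_maf))
  )
  list(geno = out, report = report)
}

#' Sample-level call-rate filter
#'
#' Keeps samples whose fraction of non-missing calls is strictly above
#' `call_rate_min`. Sample order is preserved.
#'
#' @param g a [geno()] object.
#' @param call_rate_min minimum sample call rate (exclusive). Default 0.95.
#' @return A list with `geno` and `report` as in [filter_markers()].
#' @export
filter_sample_call_rate <- function(g, call_rate_min = 0.95) {
  stopifnot(inherits(g, "geno"), n_samples(g) > 0)
  cr <- rowMeans(!is.na(g$calls))
  keep <- cr > call_rate_min
  out <- geno_subset(g, samples = which(keep))
  if (n_samples(out) == 0) {
    warning("all samples removed by QC: empty sample set")
  }
  report <- qc_report(
    axis = "sample",
    n_in = n_samples(g), n_out = n_samples(out),
    removals = c(sample_call_rate = sum(!keep))
  )
  list(geno = out, report = report)
}

#' Duplicate-sample detection from IBS
#'
#' Flags unordered sample pairs whose identity-by-state similarity is
#' strictly above `threshold` (default 0.95) as putative duplicates.
#'
#' @param ibs an [ibs_matrix()] result.
#' @param threshold IBS similarity above which a pair is flagged (exclusive).
#' @return A tibble `id1`, `id2`, `ibs`, ordered by (`id1`, `id2`) with
#'   `id1 < id2`; zero rows when no pair exceeds the threshold.
#' @export
detect_duplicates <- function(ibs, threshold = 0.95) {
  m <- ibs$ibs
  ids <- ibs$samples
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    id1 = pmin(ids[idx[, 1]], ids[idx[, 2]]),
    id2 = pmax(ids[idx[, 1]], ids[idx[, 2]]),
    ibs = m[idx]
  )
  dplyr::arrange(out, .data$id1, .data$id2)
}

#' QC report tibble
#'
#' One row per removal rule plus dimension bookkeeping; `n_in - n_out`
#' always equals the sum of `n_removed` for the axis.
#'
#' @param axis `"marker"` or `"sample"`.
#' @param n_in,n_out dimensions before/after.
#' @param removals named integer vector of per-rule removal counts.
#' @return A tibble `axis`, `rule`, `n_removed`, `n_in`, `n_out`.
#' @export
qc_report <- function(axis, n_in, n_out, removals) {
  stopifnot(n_in - n_out == sum(removals), all(removals >= 0))
  tibble::tibble(
    axis = axis,
    rule = names(removals),
    n_removed = as.integer(removals),
    n_in = as.integer(n_in),
    n_out = as.integer(n_out)
  )
}

#' Full QC pass
#'
#' Applies the filters in the package's fixed order: unmapped markers,
#' marker call rate, MAF, sample call rate, then duplicate detection on the
#' IBS of the filtered matrix. Duplicates are reported; removal (keeping the
#' pair member with the higher call rate) is opt-in.
#'
#' @inheritParams filter_markers
#' @param sample_call_rate_min minimum sample call rate (exclusive).
#' @param dup_ibs_min IBS above which a pair is a duplicate (exclusive).
#' @param remove_duplicates if `TRUE`, drop the lower-call-rate member of
#'   each flagged pair. Default `FALSE` (report only).
#' @return A list with `geno`, `report` (all rules), `duplicates` (tibble).
#' @export
qc_pipeline <- function(g, maf_min = 0.05, call_rate_min = 0.95,
                        sample_call_rate_min = 0.95, dup_ibs_min = 0.95,
                        remove_duplicates = FALSE) {
  fm <- filter_markers(g, maf_min = maf_min, call_rate_min = call_rate_min)
  fs <- filter_sample_call_rate(fm$geno, call_rate_min = sample_call_rate_min)
  g2 <- fs$geno
  dup <- detect_duplicates(ibs_matrix(g2), threshold = dup_ibs_min)
  n_dup_removed <- 0L
  if (remove_duplicates && nrow(dup) > 0) {
    cr <- rowMeans(!is.na(g2$calls))
    names(cr) <- g2$samples
    drop <- unique(ifelse(cr[dup$id1] >= cr[dup$id2], dup$id2, dup$id1))
    g2 <- geno_subset(g2, samples = setdiff(g2$samples, drop))
    n_dup_removed <- length(drop)
  }
  report <- dplyr::bind_rows(
    fm$report, fs$report,
    qc_report("sample", n_samples(fs$geno), n_samples(g2),
              c(duplicate = n_dup_removed))
  )
  list(geno = g2, report = report, duplicates = dup)
}
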