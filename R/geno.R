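#' Genotype matrix container
#'
#' A `geno` object holds diploid biallelic SNP calls for a panel of samples as
#' an integer dosage matrix (samples x markers), counting copies of `allele_b`
#' (the minor allele as observed in the data): 0, 1, 2 or `NA` for a missing
#' call. Marker metadata (name, chromosome, base-pair position, the two allele
#' codes) travels alongside as a tibble.
#'
#' @param calls integer matrix, samples in rows, markers in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are sample ids; ignored if `samples` given.
#' @param markers tibble with columns `name`, `chromosome`, `position_bp`,
#'   `allele_a`, `allele_b`. One row per column of `calls`.
#' @param samples character vector of unique sample ids, one per row of
#'   `calls`.
#'
#' @return An object of class `geno` with elements `calls`, `markers`,
#'   `samples`.
#' @export
#'
#' @examples
#' g <- geno(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   markers = tibble::tibble(
#'     name = c("snp1", "snp2"), chromosome = c("1", "1"),
#'     position_bp = c(100L, 200L), allele_a = "A", allele_b = "G"
#'   ),
#'   samples = c("s1", "s2")
#' )
#' n_markers(g)
geno <- function(calls, markers, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    stop("sample ids are required (row names of `calls` or `samples`)")
  }
  samples <- as.character(samples)
  markers <- tibble::as_tibble(markers)
  required <- c("name", "chromosome", "position_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    stop("markers tibble lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) != length(samples)) {
    stop("nrow(calls) != length(samples)")
  }
  if (ncol(calls) != nrow(markers)) {
    stop("ncol(calls) != nrow(markers)")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(markers$name)) {
    stop("duplicate marker names: ",
         paste(unique(markers$name[duplicated(markers$name)]), collapse = ", "))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing calls must be 0, 1 or 2")
  }
  if (any(markers$position_bp < 1, na.rm = TRUE)) {
    stop("position_bp must be >= 1")
  }
  same <- !is.na(markers$allele_a) & !is.na(markers$allele_b) &
    markers$allele_a == markers$allele_b
  if (any(same)) {
    stop("allele_a == allele_b at marker(s): ",
         paste(utils::head(markers$name[same], 5), collapse = ", "))
  }
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  dimnames(calls) <- list(samples, markers$name)
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "geno")
}

#' @rdname geno
#' @param x a `geno` object.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname geno
#' @export
n_markers <- function(x) nrow(x$markers)

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d samples x %d markers\n", n_samples(x), n_markers(x)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  cat(sprintf("  chromosomes: %s\n",
              paste(utils::head(unique(x$markers$chromosome), 10), collapse = " ")))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `geno` object.
#' @param samples logical/integer/character index of samples to keep.
#' @param markers logical/integer/character index of markers to keep.
#' @return A `geno` with the selected samples and markers, order preserved as
#'   given by the index.
#' @export
geno_subset <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "geno"))
  si <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  mi <- if (is.null(markers)) seq_len(n_markers(x)) else markers
  if (is.character(si)) si <- match(si, x$samples)
  if (is.character(mi)) mi <- match(mi, x$markers$name)
  geno(
    calls = x$calls[si, mi, drop = FALSE],
    markers = x$markers[mi, , drop = FALSE],
    samples = x$samples[si]
  )
}

#' Per-marker allele frequencies and call statistics
#'
#' Frequency of `allele_b` (the dosage-counted allele) per marker:
#' `q = (2 n_hom_b + n_het) / T` with `T` twice the number of non-missing
#' genotypes; `p = 1 - q` is the `allele_a` frequency. Markers with no calls
#' get `NA` frequencies.
#'
#' @param g a `geno` object.
#' @return A tibble with one row per marker: `name`, `n_called`, `T` (twice
#'   `n_called`), `p` (allele_a frequency), `q` (allele_b frequency), `maf`,
#'   `call_rate`, `het_rate` (fraction heterozygous among called).
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "geno"))
  cl <- g$calls
  n_called <- unname(colSums(!is.na(cl)))
  dosage_sum <- unname(colSums(cl, na.rm = TRUE))
  Tj <- 2L * n_called
  q <- ifelse(n_called > 0, dosage_sum / Tj, NA_real_)
  het <- unname(colSums(cl == 1L, na.rm = TRUE))
  tibble::tibble(
    name = g$markers$name,
    n_called = as.integer(n_called),
    T = as.integer(Tj),
    p = 1 - q,
    q = q,
    maf = pmin(q, 1 - q),
    call_rate = n_called / nrow(cl),
    het_rate = ifelse(n_called > 0, het / n_called, NA_real_)
  )
}
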