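#' Read PLINK-text genotypes (PED/MAP)
#'
#' Parses a whitespace-delimited PED file (six leading columns, then two
#' allele columns per marker) together with its MAP file (chromosome, marker
#' name, genetic position, base-pair position) into a [geno()] dosage matrix.
#'
#' Allele orientation is recomputed from the data, never trusted from file
#' order: at each marker `allele_a` is the major allele and `allele_b` the
#' minor by observed count, ties broken lexicographically (the alphabetically
#' smaller code becomes `allele_a`). Dosages count copies of `allele_b`. Both
#' ACGT and 1/2 allele coding are accepted; `"0"` is the only missing-allele
#' token, and a genotype with either allele missing is a missing call.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [geno()] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           col.names = c("chromosome", "name", "cm", "bp"))
  n_markers <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- strsplit(trimws(lines), "[ \t]+")
  n_tok <- lengths(tokens)
  expected <- 6L + 2L * n_markers
  if (any(n_tok != expected)) {
    bad <- which(n_tok != expected)[1]
    stop(sprintf(
      "PED row %d has %d fields; expected %d (6 + 2 x %d MAP markers)",
      bad, n_tok[bad], expected, n_markers
    ))
  }
  tok <- matrix(unlist(tokens), nrow = length(tokens), byrow = TRUE)
  samples <- tok[, 2]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in PED: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  a1 <- tok[, 6L + 2L * seq_len(n_markers) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(n_markers), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  allele_a <- allele_b <- character(n_markers)
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = n_markers)
  for (j in seq_len(n_markers)) {
    obs <- c(a1[, j], a2[, j])
    counts <- sort(table(obs[!is.na(obs)]), decreasing = TRUE)
    alleles <- names(counts)
    if (length(alleles) > 2) {
      stop(sprintf("marker %s has %d observed alleles (%s); at most 2 allowed",
                   map$name[j], length(alleles), paste(alleles, collapse = ",")))
    }
    if (length(alleles) == 0) {
      allele_a[j] <- "0"; allele_b[j] <- "."
      next
    }
    if (length(alleles) == 1) {
      allele_a[j] <- alleles[1]
      allele_b[j] <- "."  # placeholder: minor allele unobserved
      calls[, j] <- ifelse(miss[, j], NA_integer_, 0L)
      next
    }
    if (counts[1] == counts[2]) alleles <- sort(alleles)
    allele_a[j] <- alleles[1]
    allele_b[j] <- alleles[2]
    calls[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
  }

  geno(
    calls = calls,
    markers = tibble::tibble(
      name = map$name,
      chromosome = map$chromosome,
      position_bp = as.integer(map$bp),
      allele_a = allele_a,
      allele_b = allele_b
    ),
    samples = samples
  )
}

#' Write PLINK-text genotypes (PED/MAP)
#'
#' Inverse of [read_ped_map()]: dosage 0 becomes `allele_a allele_a`, 1
#' becomes `allele_a allele_b`, 2 becomes `allele_b allele_b` and missing is
#' written `0 0`. The six leading PED columns are family id = individual id =
#' the sample id, with unknown parents, sex and phenotype (`0 0 0 -9`).
#' Reading the files back yields a matrix with equal calls provided dosages
#' are minor-allele oriented (see [orient_minor()]).
#'
#' @param g a [geno()] object.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "geno"))
  map <- data.frame(
    chromosome = g$markers$chromosome,
    name = g$markers$name,
    cm = rep(0, n_markers(g)),
    bp = g$markers$position_bp
  )
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  n <- n_samples(g)
  L <- n_markers(g)
  lead <- cbind(g$samples, g$samples, "0", "0", "0", "-9")
  if (L > 0) {
    a_mat <- matrix(g$markers$allele_a, n, L, byrow = TRUE)
    b_mat <- matrix(g$markers$allele_b, n, L, byrow = TRUE)
    # dosage 0 -> "a a", 1 -> "a b", 2 -> "b b", missing -> "0 0"
    first <- ifelse(g$calls == 2L, b_mat, a_mat)
    second <- ifelse(g$calls >= 1L, b_mat, a_mat)
    first[is.na(g$calls)] <- "0"
    second[is.na(g$calls)] <- "0"
    gt <- matrix(NA_character_, n, 2L * L)
    gt[, 2L * seq_len(L) - 1L] <- first
    gt[, 2L * seq_len(L)] <- second
    rows <- cbind(lead, gt)
  } else {
    rows <- lead
  }
  writeLines(apply(rows, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Re-orient dosages to count the minor allele
#'
#' Flips markers whose counted allele has frequency above 0.5 (dosage becomes
#' `2 - dosage`, allele codes swap). At exactly 0.5 the lexicographically
#' smaller code is assigned to `allele_a`, matching [read_ped_map()]'s
#' convention, so that write/read round-trips are the identity.
#'
#' @param g a [geno()] object.
#' @return A [geno()] with every marker minor-allele oriented.
#' @export
orient_minor <- function(g) {
  stopifnot(inherits(g, "geno"))
  af <- allele_freq(g)
  flip <- !is.na(af$q) &
    (af$q > 0.5 | (af$q == 0.5 & g$markers$allele_b < g$markers$allele_a))
  if (!any(flip)) {
    return(g)
  }
  calls <- g$calls
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  markers <- g$markers
  tmp <- markers$allele_a[flip]
  markers$allele_a[flip] <- markers$allele_b[flip]
  markers$allele_b[flip] <- tmp
  geno(calls = calls, markers = markers, samples = g$samples)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Read sample-metadata and phenotype tables
#'
#' Both files are delimited text (tab or comma, detected from the header
#' line) with a header. The sample table needs columns `id`, `breed`,
#' `birth_date`, `birth_place`; the phenotype table needs `id`,
#' `body_mass_g`, `age_days`. When genotype sample ids are supplied, ids
#' present in a table but absent from the genotypes are reported in
#' `unmatched` (they are kept in the returned tibbles).
#'
#' @param samples_path path to the sample-metadata table, or `NULL`.
#' @param pheno_path path to the phenotype table, or `NULL`.
#' @param genotype_ids optional character vector of genotyped sample ids to
#'   validate against.
#' @return A list with tibbles `samples` and `phenotypes` (either may be
#'   `NULL`) and a tibble `unmatched` (`id`, `table`).
#' @export
read_tables <- function(samples_path = NULL, pheno_path = NULL,
                        genotype_ids = NULL) {
  samples <- phenos <- NULL
  unmatched <- tibble::tibble(id = character(), table = character())

  if (!is.null(samples_path)) {
    samples <- read_delim_auto(samples_path)
    need <- c("id", "breed", "birth_date", "birth_place")
    miss <- setdiff(need, names(samples))
    if (length(miss) > 0) {
      stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
    }
    samples <- samples[need]
  }
  if (!is.null(pheno_path)) {
    phenos <- read_delim_auto(pheno_path)
    need <- c("id", "body_mass_g", "age_days")
    miss <- setdiff(need, names(phenos))
    if (length(miss) > 0) {
      stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
    }
    phenos <- phenos[need]
    for (col in c("body_mass_g", "age_days")) {
      val <- suppressWarnings(as.numeric(phenos[[col]]))
      bad <- which(is.na(val) & !is.na(phenos[[col]]))
      if (length(bad) > 0) {
        stop(sprintf("phenotype table: non-numeric %s at row %d (value '%s')",
                     col, bad[1], phenos[[col]][bad[1]]))
      }
      phenos[[col]] <- val
    }
  }
  if (!is.null(genotype_ids)) {
    if (!is.null(samples)) {
      extra <- setdiff(samples$id, genotype_ids)
      if (length(extra) > 0) {
        unmatched <- dplyr::bind_rows(
          unmatched, tibble::tibble(id = extra, table = "samples"))
      }
    }
    if (!is.null(phenos)) {
      extra <- setdiff(phenos$id, genotype_ids)
      if (length(extra) > 0) {
        unmatched <- dplyr::bind_rows(
          unmatched, tibble::tibble(id = extra, table = "phenotypes"))
      }
    }
    if (nrow(unmatched) > 0) {
      message(nrow(unmatched), " table id(s) not present in the genotypes")
    }
  }
  list(samples = samples, phenotypes = phenos, unmatched = unmatched)
}
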