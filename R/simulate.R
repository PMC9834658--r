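#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with validated
#' defaults chosen to emulate a Merino-like SNP-array study: a handful of
#' breeds at controlled Balding-Nichols divergence, a within-breed pedigree
#' dominated by one heavily used sire, and a daily-weight-gain phenotype with
#' a few large-effect loci, polygenic background, birth-year and birth-place
#' cohort effects, rescaled into the 261.6-494.7 g/day range.
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param n_breeds number of breeds.
#' @param n_per_breed samples per breed (recycled to `n_breeds`).
#' @param n_markers marker count.
#' @param fst per-breed Balding-Nichols divergence F in [0, 0.5) (recycled).
#' @param missing_rate uniform genotype missingness rate. Default 0 (clean).
#' @param n_sires,n_dams,n_offspring pedigree design of the hub population.
#' @param dominant_sire_frac fraction of offspring fathered by sire 1.
#' @param qtl_var variance fractions of the planted QTLs (one per QTL).
#' @param h2_polygenic polygenic (kinship) variance fraction.
#' @param var_birth_year,var_birth_place covariate variance fractions.
#' @param n_birth_years birth-year cohorts spanned by the samples.
#' @param n_places number of farms/places of birth.
#' @param gain_range target daily-gain range in g/day.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_breeds = 3,
                       n_per_breed = 50,
                       n_markers = 2000,
                       fst = 0.05,
                       missing_rate = 0,
                       n_sires = 10,
                       n_dams = 100,
                       n_offspring = 100,
                       dominant_sire_frac = 0.6,
                       qtl_var = c(0.2),
                       h2_polygenic = 0.3,
                       var_birth_year = 0.05,
                       var_birth_place = 0.05,
                       n_birth_years = 10,
                       n_places = 5,
                       gain_range = c(261.6, 494.7)) {
  cfg <- list(
    seed = as.integer(seed), n_breeds = n_breeds,
    n_per_breed = rep_len(n_per_breed, n_breeds),
    n_markers = n_markers, fst = rep_len(fst, n_breeds),
    missing_rate = missing_rate,
    n_sires = n_sires, n_dams = n_dams, n_offspring = n_offspring,
    dominant_sire_frac = dominant_sire_frac,
    qtl_var = qtl_var, h2_polygenic = h2_polygenic,
    var_birth_year = var_birth_year, var_birth_place = var_birth_place,
    n_birth_years = n_birth_years, n_places = n_places,
    gain_range = gain_range
  )
  stopifnot(
    all(cfg$fst >= 0), all(cfg$fst < 0.5),
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$dominant_sire_frac > 0, cfg$dominant_sire_frac <= 1,
    all(cfg$qtl_var >= 0), cfg$h2_polygenic >= 0,
    sum(cfg$qtl_var) + cfg$h2_polygenic + cfg$var_birth_year +
      cfg$var_birth_place < 1,
    cfg$gain_range[1] < cfg$gain_range[2],
    cfg$n_markers > 0, all(cfg$n_per_breed > 0), cfg$n_sires >= 1
  )
  structure(cfg, class = "sim_config")
}

new_marker_panel <- function(n_markers, n_chrom = 26) {
  chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(i) {
    seq_along(i) * 50000L
  }), use.names = FALSE)
  tibble::tibble(
    name = sprintf("snp%05d", seq_len(n_markers)),
    chromosome = as.character(chrom),
    position_bp = pos,
    allele_a = "A",
    allele_b = "G"
  )
}

inject_missing <- function(calls, rate) {
  if (rate <= 0) {
    return(calls)
  }
  miss <- stats::runif(length(calls)) < rate
  calls[miss] <- NA_integer_
  calls
}

#' Simulate diverged breeds under the Balding-Nichols model
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each breed draws its
#' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral p (its
#' own p at F = 0), and genotypes are Binomial(2, p_breed) under
#' Hardy-Weinberg. F is the Weir-Cockerham Fst estimand for the breed against
#' the ancestral pool. Dosages are re-oriented so the counted allele is the
#' minor one (see [orient_minor()]). Birth year and place are assigned
#' uniformly at random for downstream covariate use.
#'
#' @param config a [sim_config()].
#' @return A list with `geno` (a [geno()]) and `samples` (tibble `id`,
#'   `breed`, `birth_date`, `birth_place`).
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_markers
  p_anc <- stats::runif(L, 0.05, 0.95)
  calls <- NULL
  ids <- breed <- character(0)
  for (b in seq_len(config$n_breeds)) {
    f <- config$fst[b]
    p_b <- if (f == 0) {
      p_anc
    } else {
      stats::rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
    nb <- config$n_per_breed[b]
    gm <- matrix(stats::rbinom(nb * L, 2L, rep(p_b, each = nb)), nrow = nb)
    calls <- rbind(calls, gm)
    ids <- c(ids, sprintf("B%d_%03d", b, seq_len(nb)))
    breed <- c(breed, rep(sprintf("breed%d", b), nb))
  }
  calls <- inject_missing(calls, config$missing_rate)
  g <- orient_minor(geno(calls, new_marker_panel(L), samples = ids))
  n <- length(ids)
  samples <- tibble::tibble(
    id = ids,
    breed = breed,
    birth_date = sprintf("%d-03-15", sample(seq_len(config$n_birth_years), n,
                                            replace = TRUE) + 2009L),
    birth_place = sprintf("farm%d", sample.int(config$n_places, n,
                                               replace = TRUE))
  )
  list(geno = g, samples = samples)
}

mendelian_gamete <- function(dosage) {
  # per-marker transmitted allele count: hom transmits its allele,
  # het transmits either with probability 1/2
  stats::rbinom(length(dosage), 1L, dosage / 2)
}

#' Simulate a hub-sire population
#'
#' Founders are drawn under Hardy-Weinberg from Uniform(0.05, 0.95) allele
#' frequencies; offspring genotypes are built by Mendelian gamete sampling
#' from their parents. One dominant sire fathers `dominant_sire_frac` of the
#' offspring; the remainder is split evenly over the other sires. Under the
#' default line-breeding design (`related_sires = TRUE`) the minor sires are
#' themselves sons of the dominant sire (out of unsampled unrelated dams),
#' the common situation when one preferred line supplies the breeding rams —
#' it is this design that turns the similarity network into a spoked wheel:
#' parent-offspring similarity stays above the connectivity threshold while
#' half-sib similarity falls below it, so the retained graph is close to the
#' pedigree tree rooted at the dominant sire. With `related_sires = FALSE`
#' the sires are mutually unrelated founders (the balanced-usage negative
#' control). Each offspring gets its own dam when `n_dams >= n_offspring`
#' (dams are sampled with replacement otherwise); dams are ungenotyped, as
#' when only one parent line is sampled.
#'
#' @param config a [sim_config()].
#' @param related_sires if `TRUE` (default), minor sires are sons of the
#'   dominant sire; if `FALSE`, all sires are unrelated founders.
#' @return A list with `geno` (sires + offspring), `pedigree` (tibble `id`,
#'   `sire`, `dam`; founder parents are recorded as `NA`), `samples`
#'   (metadata tibble as in [simulate_breeds()]), and `dominant_sire` (its
#'   sample id).
#' @export
simulate_hub_population <- function(config, related_sires = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_markers
  p <- stats::runif(L, 0.05, 0.95)
  draw_founder <- function() stats::rbinom(L, 2L, p)

  sire_ids <- sprintf("sire%02d", seq_len(config$n_sires))
  dam_ids <- sprintf("dam%03d", seq_len(config$n_dams))
  sires <- matrix(0L, config$n_sires, L)
  sires[1, ] <- draw_founder()
  sire_parent <- rep(NA_character_, config$n_sires)
  if (config$n_sires > 1) {
    for (s in seq(2L, config$n_sires)) {
      if (related_sires) {
        # minor sires are sons of the dominant sire, dams unrelated/unsampled
        sires[s, ] <- mendelian_gamete(sires[1, ]) +
          mendelian_gamete(draw_founder())
        sire_parent[s] <- sire_ids[1]
      } else {
        sires[s, ] <- draw_founder()
      }
    }
  }
  dams <- t(vapply(dam_ids, function(i) draw_founder(), integer(L)))

  n_off <- config$n_offspring
  n_dom <- round(config$dominant_sire_frac * n_off)
  sire_of <- c(rep(1L, n_dom),
               if (config$n_sires > 1 && n_off > n_dom) {
                 rep_len(seq(2L, config$n_sires), n_off - n_dom)
               } else {
                 rep(1L, n_off - n_dom)
               })
  dam_of <- if (config$n_dams >= n_off) {
    sample.int(config$n_dams, n_off, replace = FALSE)
  } else {
    sample.int(config$n_dams, n_off, replace = TRUE)
  }
  off <- matrix(0L, n_off, L)
  for (i in seq_len(n_off)) {
    off[i, ] <- mendelian_gamete(sires[sire_of[i], ]) +
      mendelian_gamete(dams[dam_of[i], ])
  }
  off_ids <- sprintf("lamb%03d", seq_len(n_off))

  calls <- inject_missing(rbind(sires, off), config$missing_rate)
  ids <- c(sire_ids, off_ids)
  g <- orient_minor(geno(calls, new_marker_panel(L), samples = ids))
  pedigree <- dplyr::bind_rows(
    tibble::tibble(id = sire_ids, sire = sire_parent, dam = NA_character_),
    tibble::tibble(id = off_ids, sire = sire_ids[sire_of],
                   dam = dam_ids[dam_of])
  )
  samples <- tibble::tibble(
    id = ids,
    breed = "hub_breed",
    birth_date = sprintf("%d-03-15",
                         sample(seq_len(config$n_birth_years),
                                length(ids), replace = TRUE) + 2009L),
    birth_place = sprintf("farm%d", sample.int(config$n_places, length(ids),
                                               replace = TRUE))
  )
  list(geno = g, pedigree = pedigree, samples = samples,
       dominant_sire = sire_ids[1])
}

#' Simulate daily-gain phenotypes over given genotypes
#'
#' Builds `y = sum_q beta_q dosage_q + birth-year effect + place effect +
#' u + e` with `u ~ MVN(0, vg K)` and i.i.d. residuals. Each component is
#' empirically standardized before weighting, so realized variance fractions
#' match the configured ones up to sampling cross-covariance. The gain is
#' then linearly rescaled into `gain_range` (g/day); a measurement age is
#' drawn uniformly from 30-80 days and body mass back-solved as
#' `daily_gain * age`, so [standardize_daily_gain()] on the emitted table
#' reproduces the simulated response exactly.
#'
#' @param g a [geno()] object.
#' @param K kinship matrix for the polygenic term (e.g. [kinship_ibs()]).
#' @param samples metadata tibble (`id`, `birth_date`, `birth_place`)
#'   aligned with `g` — its cohorts receive the covariate effects.
#' @param config a [sim_config()]; `qtl_var`, `h2_polygenic`,
#'   `var_birth_year`, `var_birth_place`, `gain_range` and `seed` are used.
#' @param qtl_markers marker names to plant QTLs on; defaults to an evenly
#'   spaced pick of `length(qtl_var)` polymorphic markers.
#' @return A list with `phenotypes` (tibble `id`, `body_mass_g`, `age_days`),
#'   `truth` (list: `qtl` tibble with marker/variance fraction/beta on the
#'   rescaled scale, realized variance fractions, scale/shift).
#' @export
simulate_phenotypes <- function(g, K, samples, config, qtl_markers = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(g, "geno"))
  set.seed(config$seed + 1L)
  n <- n_samples(g)
  nq <- length(config$qtl_var)
  af <- allele_freq(g)
  if (is.null(qtl_markers)) {
    poly <- which(!is.na(af$maf) & af$maf >= 0.1)
    if (length(poly) < nq) {
      stop("not enough polymorphic markers to place the QTLs")
    }
    qtl_markers <- g$markers$name[poly[round(seq(1, length(poly),
                                                 length.out = nq))]]
  }

  unit_scale <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  y <- rep(0, n)
  qtl_beta_std <- numeric(nq)
  for (qi in seq_len(nq)) {
    dose <- dosage_matrix(geno_subset(g, markers = qtl_markers[qi]))[, 1]
    sd_d <- stats::sd(dose)
    if (sd_d == 0) {
      stop("QTL marker ", qtl_markers[qi], " is monomorphic")
    }
    qtl_beta_std[qi] <- sqrt(config$qtl_var[qi]) / sd_d
    y <- y + unit_scale(dose) * sqrt(config$qtl_var[qi])
  }

  rows <- match(g$samples, samples$id)
  year <- factor(sub("^([0-9]{4}).*$", "\\1", samples$birth_date[rows]))
  place <- factor(samples$birth_place[rows])
  year_eff <- stats::rnorm(nlevels(year))[year]
  place_eff <- stats::rnorm(nlevels(place))[place]
  y <- y + unit_scale(year_eff) * sqrt(config$var_birth_year)
  y <- y + unit_scale(place_eff) * sqrt(config$var_birth_place)

  if (config$h2_polygenic > 0) {
    eig <- eigen(K, symmetric = TRUE)
    u <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * stats::rnorm(n))
    y <- y + unit_scale(u) * sqrt(config$h2_polygenic)
  }
  ve <- 1 - sum(config$qtl_var) - config$h2_polygenic -
    config$var_birth_year - config$var_birth_place
  y <- y + unit_scale(stats::rnorm(n)) * sqrt(ve)

  y <- as.numeric(y)
  lo <- config$gain_range[1]
  hi <- config$gain_range[2]
  scale <- (hi - lo) / diff(range(y))
  shift <- lo - min(y) * scale
  gain <- y * scale + shift

  age <- sample(30:80, n, replace = TRUE)
  phenotypes <- tibble::tibble(
    id = g$samples,
    body_mass_g = gain * age,
    age_days = age
  )
  list(
    phenotypes = phenotypes,
    truth = list(
      qtl = tibble::tibble(
        marker = qtl_markers,
        var_fraction = config$qtl_var,
        beta_gain = qtl_beta_std * scale
      ),
      scale = scale, shift = shift,
      gain = gain
    )
  )
}

#' Write a simulated study to disk
#'
#' Emits PED/MAP, a sample-metadata TSV, a phenotype TSV, a pedigree TSV
#' (hub design) and a JSON sidecar of the true simulation parameters —
#' everything [run_pipeline()] consumes.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param design `"hub"` (single breed around a dominant sire, the default)
#'   or `"breeds"` (multi-breed divergence panel).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_study <- function(config, dir, design = c("hub", "breeds")) {
  design <- match.arg(design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- if (design == "hub") {
    simulate_hub_population(config)
  } else {
    simulate_breeds(config)
  }
  K <- kinship_ibs(ibs_matrix(sim$geno))
  ph <- simulate_phenotypes(sim$geno, K, sim$samples, config)

  paths <- list(
    ped = file.path(dir, "genotypes.ped"),
    map = file.path(dir, "genotypes.map"),
    samples = file.path(dir, "samples.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_ped_map(sim$geno, paths$ped, paths$map)
  readr::write_tsv(sim$samples, paths$samples)
  readr::write_tsv(ph$phenotypes, paths$phenotypes)
  truth <- list(
    design = design, seed = config$seed,
    qtl = ph$truth$qtl,
    gain_scale = ph$truth$scale, gain_shift = ph$truth$shift
  )
  if (design == "hub") {
    paths$pedigree <- file.path(dir, "pedigree.tsv")
    readr::write_tsv(sim$pedigree, paths$pedigree)
    truth$dominant_sire <- sim$dominant_sire
  }
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
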