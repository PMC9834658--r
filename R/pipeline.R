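#' Pipeline run configuration
#'
#' @param ped,map paths to the PLINK-text genotypes.
#' @param samples path to the sample-metadata table (id, breed, birth_date,
#'   birth_place), or `NULL`.
#' @param phenotypes path to the phenotype table (id, body_mass_g,
#'   age_days), or `NULL`; supplying it switches the association stage on.
#' @param out_dir output directory.
#' @param maf_min,marker_call_rate_min,sample_call_rate_min,dup_ibs_min QC
#'   thresholds (all exclusive bounds, see [qc_pipeline()]).
#' @param network_threshold `"auto"` (largest threshold keeping the IBS
#'   graph connected) or a numeric value between 0 and 1.
#' @param network_rule edge rule, `"ge"` or `"gt"`.
#' @param remove_top hubs to remove in the re-analysis stage.
#' @param highlight_percentile edge-weight percentile drawn thick.
#' @param pca_k number of principal components.
#' @param max_cofactors forward-selection cap for the association scan.
#' @param run_gwas force the association stage on/off; default: on when a
#'   phenotype path is given.
#' @param seed RNG seed recorded in the manifest and set before the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ped, map, samples = NULL, phenotypes = NULL,
                       out_dir = tempfile("flocknet_run_"),
                       maf_min = 0.05, marker_call_rate_min = 0.95,
                       sample_call_rate_min = 0.95, dup_ibs_min = 0.95,
                       network_threshold = "auto", network_rule = "ge",
                       remove_top = 1, highlight_percentile = 85,
                       pca_k = 10, max_cofactors = 10,
                       run_gwas = !is.null(phenotypes), seed = 1) {
  stopifnot(
    maf_min >= 0, maf_min <= 1, marker_call_rate_min >= 0,
    marker_call_rate_min <= 1, sample_call_rate_min >= 0,
    sample_call_rate_min <= 1, dup_ibs_min >= 0, dup_ibs_min <= 1,
    identical(network_threshold, "auto") ||
      (is.numeric(network_threshold) && network_threshold >= 0 &&
         network_threshold <= 1)
  )
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: genotype input, QC (markers then samples then
#' duplicate report), breed diversity, pairwise Fst (when at least two
#' breeds are present), PCA of the standardized relationship matrix, the IBS
#' similarity network at the chosen threshold with summary, hub removal and
#' GraphML/edge-list export, phenotype standardization, and the multi-locus
#' mixed-model association scan. Every table is written as TSV with a header
#' under `out_dir`, and a JSON manifest records the package version,
#' parameters, seed and per-stage row counts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`geno`, `qc`,
#'   `diversity`, `fst`, `pca`, `ibs`, `network`, `network_summary`,
#'   `hub_removal`, `phenotypes`, `gwas`, `manifest`) and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  paths <- list()
  manifest <- list(
    package = "flocknet",
    version = as.character(utils::packageVersion("flocknet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("ped", "map", "samples",
                                                 "phenotypes", "out_dir"))],
    stages = list()
  )
  note <- function(stage_name, ...) {
    manifest$stages[[stage_name]] <<- list(...)
  }

  g_raw <- stage("genotype_io", read_ped_map(config$ped, config$map))
  note("genotype_io", n_samples = n_samples(g_raw), n_markers = n_markers(g_raw))

  tables <- stage("genotype_io", read_tables(config$samples, config$phenotypes,
                                             genotype_ids = g_raw$samples))

  qc <- stage("qc", qc_pipeline(
    g_raw, maf_min = config$maf_min,
    call_rate_min = config$marker_call_rate_min,
    sample_call_rate_min = config$sample_call_rate_min,
    dup_ibs_min = config$dup_ibs_min
  ))
  g <- qc$geno
  readr::write_tsv(qc$report, paths$qc_report <- out("qc_report.tsv"))
  readr::write_tsv(qc$duplicates, paths$duplicates <- out("duplicates.tsv"))
  note("qc", n_samples = n_samples(g), n_markers = n_markers(g),
       n_duplicate_pairs = nrow(qc$duplicates))

  diversity <- fst <- NULL
  if (!is.null(tables$samples)) {
    diversity <- stage("diversity", breed_diversity(g, tables$samples))
    readr::write_tsv(diversity, paths$diversity <- out("diversity.tsv"))
    note("diversity", n_breeds = nrow(diversity))

    breeds_ok <- diversity$breed[diversity$n_samples >= 2]
    if (length(breeds_ok) >= 2) {
      fst <- stage("fst", pairwise_fst(g, tables$samples))
      readr::write_tsv(fst$pairs, paths$fst <- out("fst_pairs.tsv"))
      note("fst", n_pairs = nrow(fst$pairs))
    }
  }

  inbreeding <- stage("diversity", individual_inbreeding(g))
  readr::write_tsv(inbreeding, paths$inbreeding <- out("individual_inbreeding.tsv"))

  pca <- stage("pca", pca_standardized_grm(g, k = min(config$pca_k,
                                                      n_samples(g) - 1)))
  readr::write_tsv(pca$scores, paths$pca_scores <- out("pca_scores.tsv"))
  readr::write_tsv(tidy(pca), paths$pca_eigen <- out("pca_eigenvalues.tsv"))
  note("pca", k = length(pca$eigenvalues))

  ibs <- stage("ibs", ibs_matrix(g))
  readr::write_tsv(ibs_pairs(ibs), paths$ibs <- out("ibs_pairs.tsv"))

  thr <- if (identical(config$network_threshold, "auto")) {
    stage("network", connectivity_threshold(ibs))
  } else {
    config$network_threshold
  }
  net <- stage("network", build_network(ibs, thr, rule = config$network_rule))
  summ <- stage("network", summarize_network(net))
  hub <- stage("network", hub_removal_analysis(net, k = config$remove_top))
  readr::write_tsv(network_edges(net, config$highlight_percentile),
                   paths$edges <- out("network_edges.tsv"))
  readr::write_tsv(summ$betweenness, paths$betweenness <- out("betweenness.tsv"))
  stage("network", export_graph(net, paths$graphml <- out("network.graphml"),
                                config$highlight_percentile))
  net_summary <- list(
    threshold = thr, rule = config$network_rule,
    before = as.list(glance(summ)),
    removed = hub$removed,
    after = as.list(glance(hub$after))
  )
  jsonlite::write_json(net_summary, paths$network_summary <- out("network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  note("network", threshold = thr, n_edges = summ$n_edges,
       diameter = summ$diameter)

  phenotypes <- gwas <- NULL
  if (config$run_gwas) {
    if (is.null(tables$phenotypes)) {
      stage("gwas", stop("association scan requested but no phenotype table given"))
    }
    phenotypes <- stage("phenotype", standardize_daily_gain(tables$phenotypes))
    readr::write_tsv(phenotypes, paths$phenotypes <- out("phenotypes_standardized.tsv"))
    note("phenotype", n_records = nrow(phenotypes),
         n_accepted = sum(phenotypes$accepted))

    gwas <- stage("gwas", {
      ph <- phenotypes[phenotypes$accepted & phenotypes$id %in% g$samples, ]
      gg <- geno_subset(g, samples = ph$id)
      K <- kinship_ibs(ibs_matrix(gg))
      X0 <- if (!is.null(tables$samples)) {
        covariate_design(tables$samples, ph$id)
      } else {
        matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
      }
      mlmm_stepwise(ph$daily_gain_g, X0, K, gg,
                    max_cofactors = config$max_cofactors)
    })
    readr::write_tsv(tidy(gwas), paths$gwas <- out("association_results.tsv"))
    note("gwas", n_markers = nrow(gwas$results),
         n_cofactors = length(gwas$cofactors))
  }

  jsonlite::write_json(manifest, paths$manifest <- out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(
    geno = g, qc = qc, diversity = diversity, fst = fst, pca = pca,
    ibs = ibs, network = net, network_summary = summ, hub_removal = hub,
    inbreeding = inbreeding, phenotypes = phenotypes, gwas = gwas,
    manifest = manifest, paths = paths
  ))
}
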