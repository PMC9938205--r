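#' @include AllClasses.R synthetic-data.R genome-metrics.R abundance.R
#' @include transcription.R aai.R correlation.R cooccurrence.R
NULL

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.read_matrix_tsv <- function(path) {
  d <- .read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Assemble a pipeline configuration
#'
#' Either a `simulate` block (arguments for [simulationConfig()]) or a set
#' of input file paths (`samples`, `mags`, `scg`, `coverage`, `genes`,
#' `transcripts`, `libsizes`, `hits`) must be given. Thresholds default to
#' the values used throughout the package.
#'
#' @param simulate `NULL`, or a list of [simulationConfig()] arguments.
#' @param inputs `NULL`, or a named list of input TSV paths.
#' @param seed integer seed for every source of randomness.
#' @param rho_min,p_max network thresholds.
#' @param confirm_rho cohort confirmation threshold.
#' @param alpha correlation-screen significance level.
#' @param min_completeness,max_contamination quality filter.
#' @param out_dir output directory (`NULL`: no files written).
#' @return config list of class `"usmag_pipeline_config"`.
#' @export
pipelineConfig <- function(simulate = list(), inputs = NULL, seed = 1L,
                           rho_min = 0.8, p_max = 0.001, confirm_rho = 0.8,
                           alpha = 0.05, min_completeness = 0.5,
                           max_contamination = 0.05, out_dir = NULL) {
  stopifnot(rho_min > 0, rho_min < 1, p_max > 0, p_max < 1,
            confirm_rho > 0, confirm_rho <= 1, alpha > 0, alpha < 1)
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or input paths are required")
  if (!is.null(inputs)) {
    need <- c("samples", "mags", "scg", "coverage", "genes",
              "transcripts", "libsizes", "hits")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    for (f in unlist(inputs))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(simulate = simulate, inputs = inputs,
                 seed = as.integer(seed), rho_min = rho_min, p_max = p_max,
                 confirm_rho = confirm_rho, alpha = alpha,
                 min_completeness = min_completeness,
                 max_contamination = max_contamination, out_dir = out_dir),
            class = "usmag_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [pipelineConfig()] arguments.
#' @return config list of class `"usmag_pipeline_config"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the input tables, then runs genome quality metrics,
#' abundance normalization + enrichment, transcription summaries, AAI
#' novelty, the environmental correlation screen, and co-occurrence
#' network/cohort detection. All stage outputs are returned and, when
#' `out_dir` is set, written as TSVs together with a JSON run manifest
#' (config hash, seed, row counts).
#'
#' @param config a `"usmag_pipeline_config"` (see [pipelineConfig()]) or a
#'   path to a YAML file.
#' @return named list of stage results (class `"usmag_pipeline_result"`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "usmag_pipeline_config"))
  if (!is.null(config$simulate)) {
    simcfg <- do.call(simulationConfig,
                      c(list(seed = config$seed), config$simulate))
    sim <- simulateCommunity(simcfg)
    samples <- sim$samples; mags <- sim$mags; scg <- sim$scg
    coverage <- sim$coverage; genes <- sim$genes
    tcounts <- sim$transcripts$counts
    libsizes <- sim$transcripts$library_sizes
    condition <- sim$transcripts$condition
    hits <- sim$hits
  } else {
    sim <- NULL
    samples <- .read_tsv(config$inputs$samples)
    mags <- .read_tsv(config$inputs$mags)
    scg <- .read_tsv(config$inputs$scg)
    coverage <- .read_matrix_tsv(config$inputs$coverage)
    genes <- .read_tsv(config$inputs$genes)
    tcounts <- .read_matrix_tsv(config$inputs$transcripts)
    lib <- .read_tsv(config$inputs$libsizes)
    libsizes <- lib$library_size
    condition <- lib$condition
    hits <- .read_tsv(config$inputs$hits)
  }
  coverage <- coverage[, samples$sample_id, drop = FALSE]

  ## genome metrics
  metrics <- genomeMetrics(mags, scg = NULL)  # completeness as provided
  metrics_scg <- genomeMetrics(
    mags[isUltraSmall(mags$group), , drop = FALSE], scg = scg)
  quality <- qualityFilter(metrics, config$min_completeness,
                           config$max_contamination)

  ## abundance
  ae <- AbundanceExperiment(coverage, samples, stage = "counts")
  rel <- relativeAbundance(normalizeCounts(ae))
  redox <- classifyRedox(samples$DO)
  oxic_ids <- samples$sample_id[redox == "oxic"]
  nonoxic_ids <- setdiff(samples$sample_id, oxic_ids)
  plank_ids <- samples$sample_id[samples$fraction == samples$fraction[1]]
  att_ids <- setdiff(samples$sample_id, plank_ids)
  enr_do <- enrichmentFactors(rel, oxic_ids, nonoxic_ids,
                              grouping = "oxic-vs-dysoxic")
  enr_fr <- enrichmentFactors(rel, plank_ids, att_ids,
                              grouping = "planktonic-vs-attached")
  us_ids <- metrics$mag_id[isUltraSmall(metrics$group)]
  relm <- assay(rel)
  us_fraction <- groupFraction(rel, intersect(us_ids, rownames(relm)))
  bc <- brayCurtis(rel)

  ## transcription (oxic is the reference/numerator condition when present)
  lev <- unique(condition)
  condition <- factor(condition,
                      levels = c(intersect("oxic", lev),
                                 setdiff(lev, "oxic")))
  te <- TranscriptExperiment(tcounts, genes, libsizes, condition)
  tpm <- transcriptTpm(te)
  magx <- magExpression(tpm, genes, genomeMetrics(mags), TRUE)
  catprop <- categoryConditionProportion(tpm, genes, condition)
  excl <- exclusiveDetection(tpm, condition, "gene")
  fold <- conditionFoldChange(magx$totals, condition)
  unannot <- annotatedFraction(tpm, genes, mags)
  top <- topExpressed(tpm, genes, k = 20)

  ## AAI novelty: per genome, max AAI against every other genome in the
  ## hit table
  genomes <- sort(unique(c(hits$query_genome, hits$subject_genome)))
  novelty <- do.call(rbind, lapply(genomes, function(g)
    noveltySummary(hits, g, setdiff(genomes, g))))

  ## correlations vs environment (ultra-small MAGs)
  env_cols <- intersect(c("DO", "DOC", "nitrate_N", "pH", "sulfate", "ORP",
                          "temperature", "DRP", "conductivity"),
                        colnames(samples))
  relm_us <- relm[intersect(us_ids, rownames(relm)), , drop = FALSE]
  screen <- correlationScreen(relm_us, samples[, env_cols, drop = FALSE],
                              method = "spearman", alpha = config$alpha)

  ## co-occurrence
  net <- buildNetwork(relm_us, config$rho_min, config$p_max)
  comps <- networkComponents(net)
  cohorts <- detectCohorts(relm_us, config$confirm_rho)
  consistency <- cohortConsistency(cohorts, enr_fr, enr_do)

  result <- structure(list(
    config = config, simulation = sim, samples = samples,
    metrics = metrics, metrics_scg = metrics_scg, quality = quality,
    relative_abundance = rel, enrichment_do = enr_do,
    enrichment_fraction = enr_fr, ultrasmall_fraction = us_fraction,
    bray_curtis = bc,
    tpm = tpm, mag_expression = magx, category_proportions = catprop,
    exclusive = excl, fold_change = fold, unannotated_percent = unannot,
    top_expressed = top, novelty = novelty, screen = screen,
    network = net, components = comps, cohorts = cohorts,
    consistency = consistency), class = "usmag_pipeline_result")
  if (!is.null(config$out_dir)) writePipelineResult(result, config$out_dir)
  result
}

#' Write pipeline outputs as TSVs plus a JSON manifest
#' @param result a `"usmag_pipeline_result"` from [runPipeline()].
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
writePipelineResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE) {
    if (rn) x <- data.frame(id = rownames(x), x, check.names = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    stats::setNames(nrow(x), f)
  }
  if (!is.null(result$simulation))
    writeSimulation(result$simulation, file.path(dir, "inputs"))
  counts <- c(
    wt(result$metrics, "genome_metrics.tsv"),
    wt(result$quality, "quality_filtered.tsv"),
    wt(assay(result$relative_abundance), "relative_abundance.tsv", TRUE),
    wt(result$enrichment_do, "enrichment_oxic_vs_dysoxic.tsv"),
    wt(result$enrichment_fraction, "enrichment_planktonic_vs_attached.tsv"),
    wt(result$bray_curtis, "bray_curtis.tsv", TRUE),
    wt(result$mag_expression$totals, "mag_expression.tsv", TRUE),
    wt(result$category_proportions, "category_proportions.tsv"),
    wt(result$fold_change, "mag_fold_change.tsv"),
    wt(result$novelty, "novelty_summary.tsv"),
    wt(result$screen$entries, "correlations.tsv"),
    wt(networkEdges(result$network), "network_edges.tsv"),
    wt(cohortAssignment(result$cohorts), "cohorts.tsv"),
    wt(result$consistency$per_cohort, "cohort_consistency.tsv"))
  g <- asIgraph(result$network)
  igraph::write_graph(g, file.path(dir, "network.graphml"),
                      format = "graphml")
  cfg <- result$config
  cfg$out_dir <- NULL
  manifest <- list(
    seed = cfg$seed,
    config_hash = as.character(sum(utf8ToInt(paste(
      utils::capture.output(utils::str(cfg)), collapse = "")))),
    n_metagenome_samples = nrow(result$samples),
    n_transcriptome_samples = ncol(result$tpm),
    row_counts = as.list(counts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
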