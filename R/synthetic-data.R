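#' @include AllClasses.R genome-metrics.R
NULL

.COG_CATEGORIES <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                     "N", "O", "P", "T", "U", "V")
.GENE_NAMES <- c("rpoB", "rpoC", "gyrA", "gyrB", "recA", "ftsZ", "secY",
                 "tuf", "fusA", "infB", "nusA", "pilB", "pilC", "pilT",
                 "sodA", "trxA", "hicA", "hicB", "cspA", "cspB", "cspC",
                 "dnaK", "groL", "rplB", "rpsC")

#' Configuration for the synthetic groundwater community generator
#'
#' Defaults reproduce the study design the pipeline targets: 16 metagenome
#' samples (4 sites x 2 wells x {groundwater, sediment-enriched}), ~200
#' ultra-small MAGs with ~1 +/- 0.4 Mbp genomes plus larger background
#' MAGs, planted co-occurrence cohorts of 2-20 members with one dominant
#' site each, fourfold oxygen/fraction enrichment effects, 6 transcriptome
#' samples (2 oxic, 4 dysoxic), and physicochemistry spanning DO 0.37-7.5,
#' DOC 0-26 and nitrate-N 0.45-12.6 g/m3.
#'
#' @param seed integer seed; the same config (including seed) reproduces
#'   bit-identical outputs.
#' @param n_sites,wells_per_site,fractions sampling design (default 4 x 2 x
#'   {groundwater, sediment-enriched}).
#' @param n_ultrasmall_mags,n_background_mags genome counts.
#' @param n_cohorts,cohort_size_range planted cohorts; sizes are drawn
#'   uniformly in the range and trimmed so the total stays within
#'   `n_ultrasmall_mags`.
#' @param abundance_noise_cv within-cohort multiplicative noise CV.
#' @param enrichment_effect fold effect applied in a MAG's preferred
#'   condition.
#' @param site_effect fold elevation of a cohort's profile at its dominant
#'   site.
#' @param n_transcriptome_samples transcriptome samples; the first
#'   `n_oxic_transcriptomes` are oxic.
#' @param n_oxic_transcriptomes number of oxic transcriptome samples.
#' @param genes_per_mag_range genes simulated per MAG.
#' @param library_size_range metagenome sequencing depths, drawn uniformly
#'   (a fivefold default range so depth normalization matters).
#' @param nb_dispersion negative-binomial dispersion of transcript counts.
#' @param category_effect_range per-COG-category oxic:dysoxic expression
#'   ratios are drawn log-uniformly from this range; `c(1, 1)` plants no
#'   category effect.
#' @param mag_activity_fold central oxic:dysoxic activity fold of
#'   oxygen-preferring MAGs (dysoxic-preferring MAGs get its inverse);
#'   `1` plants no per-MAG activity effect.
#' @param env_ranges named list of `(min, max)` physicochemistry ranges.
#' @param aai_pairs `data.frame(query_genome, subject_genome, true_aai,
#'   n_pairs)` of planted proteome comparisons.
#' @param aai_sd per-hit identity standard deviation around the true AAI.
#' @return validated config list of class `"usmag_sim_config"`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_sites = 4L,
                             wells_per_site = 2L,
                             fractions = c("groundwater", "sediment-enriched"),
                             n_ultrasmall_mags = 200L,
                             n_background_mags = 100L,
                             n_cohorts = 20L,
                             cohort_size_range = c(2L, 20L),
                             abundance_noise_cv = 0.2,
                             enrichment_effect = 4.0,
                             site_effect = 10,
                             n_transcriptome_samples = 6L,
                             n_oxic_transcriptomes = 2L,
                             genes_per_mag_range = c(600L, 1200L),
                             library_size_range = c(1e6, 5e6),
                             nb_dispersion = 0.3,
                             category_effect_range = c(0.25, 4),
                             mag_activity_fold = 8,
                             env_ranges = list(
                               DO = c(0.37, 7.5),
                               DOC = c(0, 26),
                               nitrate_N = c(0.45, 12.6),
                               pH = c(5.9, 7.9),
                               sulfate = c(1, 48),
                               ORP = c(-150, 250),
                               temperature = c(11, 17),
                               DRP = c(0.005, 0.2),
                               conductivity = c(10, 60)),
                             aai_pairs = data.frame(
                               query_genome = c("qgen1", "qgen1", "qgen2"),
                               subject_genome = c("ref1", "ref2", "ref3"),
                               true_aai = c(55, 40, 75),
                               n_pairs = 200L),
                             aai_sd = 3) {
  cfg <- list(seed = as.integer(seed) %% .Machine$integer.max,
              n_sites = as.integer(n_sites),
              wells_per_site = as.integer(wells_per_site),
              fractions = fractions,
              n_ultrasmall_mags = as.integer(n_ultrasmall_mags),
              n_background_mags = as.integer(n_background_mags),
              n_cohorts = as.integer(n_cohorts),
              cohort_size_range = as.integer(cohort_size_range),
              abundance_noise_cv = abundance_noise_cv,
              enrichment_effect = enrichment_effect,
              site_effect = site_effect,
              n_transcriptome_samples = as.integer(n_transcriptome_samples),
              n_oxic_transcriptomes = as.integer(n_oxic_transcriptomes),
              genes_per_mag_range = as.integer(genes_per_mag_range),
              library_size_range = library_size_range,
              nb_dispersion = nb_dispersion,
              category_effect_range = category_effect_range,
              mag_activity_fold = mag_activity_fold,
              env_ranges = env_ranges,
              aai_pairs = aai_pairs,
              aai_sd = aai_sd)
  ranges <- c(list(cohort_size_range = cfg$cohort_size_range,
                   genes_per_mag_range = cfg$genes_per_mag_range,
                   library_size_range = cfg$library_size_range),
              cfg$env_ranges)
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      stop(nm, ": min must be <= max")
  stopifnot(cfg$category_effect_range[1] > 0, cfg$mag_activity_fold >= 1,
            cfg$abundance_noise_cv >= 0, cfg$enrichment_effect > 0,
            cfg$n_sites >= 1, cfg$wells_per_site >= 1,
            length(cfg$fractions) >= 1,
            cfg$n_oxic_transcriptomes >= 1,
            cfg$n_oxic_transcriptomes < cfg$n_transcriptome_samples)
  if (cfg$n_cohorts * cfg$cohort_size_range[1] > cfg$n_ultrasmall_mags)
    stop("n_cohorts x minimum cohort size exceeds n_ultrasmall_mags")
  class(cfg) <- "usmag_sim_config"
  cfg
}

.stage_seed <- function(config, offset) {
  set.seed((config$seed * 7L + offset) %% .Machine$integer.max)
}

# mean-1 lognormal noise with a given coefficient of variation
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the metagenome sample table with physicochemistry
#'
#' Sites are spread evenly across the DO range (guaranteeing at least one
#' oxic, DO > 3, and one dysoxic site when the range straddles the oxic
#' bound); other parameters are drawn per site within their ranges with
#' small within-site jitter. Each well contributes one sample per fraction.
#'
#' @param config a [simulationConfig()].
#' @return `data.frame`: `sample_id`, `site`, `well`, `fraction`, `redox`,
#'   and one column per environmental parameter.
#' @export
generateSamples <- function(config) {
  .stage_seed(config, 1L)
  rng <- config$env_ranges
  if (config$n_sites >= 2 && (rng$DO[2] <= 3 || rng$DO[1] > 3))
    stop("DO range must straddle the oxic bound (3 g/m3) to place both ",
         "oxic and dysoxic sites")
  sites <- paste0("site", seq_len(config$n_sites))
  do_site <- if (config$n_sites == 1) mean(rng$DO) else
    seq(rng$DO[1], rng$DO[2], length.out = config$n_sites)
  grid <- expand.grid(fraction = config$fractions,
                      well = seq_len(config$wells_per_site),
                      site = seq_len(config$n_sites),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("site", "well", "fraction")]
  n <- nrow(grid)
  env_site <- lapply(rng, function(r)
    stats::runif(config$n_sites, r[1], r[2]))
  env_site$DO <- do_site
  env <- lapply(names(rng), function(p) {
    v <- env_site[[p]][grid$site] +
      stats::rnorm(n, 0, 0.02 * diff(rng[[p]]))
    v <- pmin(pmax(v, rng[[p]][1]), rng[[p]][2])
    if (p == "DO") {  # jitter must not flip a site across the oxic bound
      oxic_site <- do_site[grid$site] > 3
      v[oxic_site] <- pmax(v[oxic_site], 3 + 1e-6)
      v[!oxic_site] <- pmin(v[!oxic_site], 3)
    }
    v
  })
  names(env) <- names(rng)
  frac_tag <- ifelse(grid$fraction == config$fractions[1], "gw", "sed")
  out <- data.frame(
    sample_id = sprintf("s%dw%d_%s", grid$site, grid$well, frac_tag),
    site = sites[grid$site],
    well = sprintf("s%dw%d", grid$site, grid$well),
    fraction = grid$fraction,
    as.data.frame(env))
  out$redox <- as.character(classifyRedox(out$DO))
  out
}

#' Generate MAG metadata, SCG profiles and size ground truth
#'
#' Ultra-small MAGs draw true genome sizes from N(1 Mbp, 0.4 Mbp) truncated
#' at 0.4 Mbp, with lineage groups in study-like proportions
#' (Patescibacteria-dominated); background MAGs are 2-6 Mbp. Completeness
#' is uniform on \[0.5, 1\], contamination on \[0, 0.05\]; marker presence is
#' binomial at the completeness, duplication binomial at the contamination,
#' and `bin_size = true_size * completeness * (1 + contamination)`.
#'
#' @param config a [simulationConfig()].
#' @return list: `mags` (`mag_id`, `group`, `bin_size`, `completeness`,
#'   `contamination`), `scg` (long format: `mag_id`, `marker_id`, `copies`,
#'   `scg_set`), `truth` (`mag_id`, `true_size`, `ultra_small`).
#' @export
generateMags <- function(config) {
  .stage_seed(config, 2L)
  n_us <- config$n_ultrasmall_mags
  n_bg <- config$n_background_mags
  groups_us <- sample(c("Patescibacteria", "Dependentiae",
                        "DPANN-Nanoarchaeota", "DPANN-Micrarchaeota",
                        "DPANN-Altiarchaeota"),
                      n_us, replace = TRUE,
                      prob = c(0.79, 0.03, 0.13, 0.045, 0.005))
  true_us <- stats::rnorm(n_us, 1e6, 4e5)
  while (any(true_us < 4e5))
    true_us[true_us < 4e5] <- stats::rnorm(sum(true_us < 4e5), 1e6, 4e5)
  true_bg <- stats::runif(n_bg, 2e6, 6e6)
  mags <- data.frame(
    mag_id = c(sprintf("usmag%03d", seq_len(n_us)),
               sprintf("bgmag%03d", seq_len(n_bg))),
    group = c(groups_us, rep("other", n_bg)),
    completeness = stats::runif(n_us + n_bg, 0.5, 1),
    contamination = stats::runif(n_us + n_bg, 0, 0.05))
  true_size <- c(true_us, true_bg)
  mags$bin_size <- round(true_size * mags$completeness *
                           (1 + mags$contamination))
  mags <- mags[, c("mag_id", "group", "bin_size", "completeness",
                   "contamination")]
  scg <- do.call(rbind, lapply(seq_len(n_us), function(i) {
    set_lab <- scgSetForGroup(mags$group[i])
    size <- scgSetSize(set_lab)
    present <- stats::runif(size) < mags$completeness[i]
    copies <- as.integer(present)
    copies[present] <- copies[present] +
      stats::rbinom(sum(present), 1, mags$contamination[i])
    data.frame(mag_id = mags$mag_id[i],
               marker_id = sprintf("%s_m%02d", set_lab, seq_len(size)),
               copies = copies, scg_set = set_lab)[copies > 0, ]
  }))
  truth <- data.frame(mag_id = mags$mag_id, true_size = true_size,
                      ultra_small = c(rep(TRUE, n_us), rep(FALSE, n_bg)))
  list(mags = mags, scg = scg, truth = truth)
}

# draw cohort sizes within range summing to <= budget (deterministic trim)
.cohort_sizes <- function(n_cohorts, range, budget) {
  sizes <- sample(seq(range[1], range[2]), n_cohorts, replace = TRUE)
  while (sum(sizes) > budget) {
    i <- which.max(sizes)
    if (sizes[i] <= range[1]) stop("cohorts cannot fit the MAG budget")
    sizes[i] <- sizes[i] - 1L
  }
  sizes
}

#' Generate the MAG x sample coverage matrix with planted structure
#'
#' Each cohort draws a log-normal base profile elevated `site_effect`-fold
#' at one dominant site; members multiply it by mean-1 log-normal noise
#' (CV `abundance_noise_cv`). MAGs carry an enrichment label (oxic,
#' dysoxic, fraction-planktonic, fraction-attached, or neutral; shared
#' within a cohort) and are multiplied by `enrichment_effect` in their
#' preferred samples. Background MAGs get independent profiles with larger
#' mass. Reads are multinomial per sample at depths drawn uniformly from
#' `library_size_range`, so column totals differ and depth normalization is
#' non-trivial.
#'
#' @param config a [simulationConfig()].
#' @param samples from [generateSamples()].
#' @param mags,truth from [generateMags()].
#' @return list: `coverage` (MAG x sample integer matrix whose column sums
#'   equal the drawn depths), `truth` (`mag_id`, `cohort`,
#'   `enrichment_label`, `dominant_site`).
#' @export
generateCoverage <- function(config, samples, mags, truth) {
  .stage_seed(config, 3L)
  n_samp <- nrow(samples)
  us_ids <- truth$mag_id[truth$ultra_small]
  bg_ids <- truth$mag_id[!truth$ultra_small]
  sizes <- .cohort_sizes(config$n_cohorts, config$cohort_size_range,
                         length(us_ids))
  member_pool <- sample(us_ids)
  cohort_of <- stats::setNames(rep(NA_character_, length(us_ids)), us_ids)
  cohort_of[member_pool[seq_len(sum(sizes))]] <-
    rep(sprintf("true%03d", seq_along(sizes)), sizes)
  sites <- unique(samples$site)
  oxic_samp <- samples$DO > 3
  plank_samp <- samples$fraction == config$fractions[1]
  site_oxic <- vapply(sites, function(s)
    any(oxic_samp[samples$site == s]), TRUE)
  labels <- c("oxic", "dysoxic", "fraction-planktonic", "fraction-attached",
              "neutral")
  label_weight <- stats::setNames(c(0.3, 0.2, 0.15, 0.15, 0.2), labels)
  # a cohort's dominant site is drawn consistently with its oxygen
  # preference (site-level DO classes are what create that preference)
  allowed_sites <- function(lab) {
    pool <- switch(lab,
                   "oxic" = sites[site_oxic],
                   "dysoxic" = sites[!site_oxic],
                   sites)
    if (!length(pool)) sites else pool
  }
  pick_site <- function(lab) {
    pool <- allowed_sites(lab)
    pool[sample.int(length(pool), 1)]
  }
  # cohorts are niche-adapted populations: each is planted in its own
  # (preference label, dominant site) niche. Two cohorts sharing both are
  # rank-indistinguishable at this sample size, so niches are drawn
  # without replacement and recycled only when more cohorts are requested
  # than niches exist.
  niches <- do.call(rbind, lapply(labels, function(l)
    data.frame(label = l, site = allowed_sites(l))))
  w_niche <- label_weight[niches$label] /
    table(niches$label)[niches$label]
  draw <- unlist(lapply(seq_len(ceiling(length(sizes) / nrow(niches))),
                        function(i) sample.int(nrow(niches), nrow(niches),
                                               prob = w_niche)))
  niche_of <- niches[draw[seq_along(sizes)], ]
  label_of_cohort <- stats::setNames(niche_of$label,
                                     sprintf("true%03d", seq_along(sizes)))
  dominant <- stats::setNames(niche_of$site, names(label_of_cohort))
  pref_mask <- function(label) switch(label,
    "oxic" = oxic_samp, "dysoxic" = !oxic_samp,
    "fraction-planktonic" = plank_samp,
    "fraction-attached" = !plank_samp,
    "neutral" = rep(FALSE, n_samp))
  wells <- unique(samples$well)
  base_profile <- function(dom_site) {
    # the base abundance is mostly a property of the well water (shared by
    # the well's paired groundwater/sediment-enriched samples, so it
    # cancels out of fraction contrasts), plus a small per-sample jitter
    # that keeps within-well sample ranks base-determined. Log-bases are
    # centered within each site so that which site dominates a cohort is
    # decided by the site effect alone, never by base-draw luck; the
    # remaining within-site well contrast and the jitter are shared by
    # cohort members and independent between cohorts -- they are what
    # keeps cohorts with overlapping niches distinguishable.
    lw <- stats::rnorm(length(wells), 0, 1.5)
    site_of_well <- samples$site[match(wells, samples$well)]
    lw <- lw - stats::ave(lw, site_of_well)
    per_well <- stats::setNames(exp(lw), wells)
    mult <- ifelse(samples$site == dom_site, config$site_effect, 1)
    unname(per_well[samples$well]) * mult *
      stats::rlnorm(n_samp, meanlog = 0, sdlog = 0.4)
  }
  cohort_base <- lapply(names(dominant), function(co) base_profile(dominant[co]))
  names(cohort_base) <- names(dominant)
  mag_label <- character(length(us_ids)); names(mag_label) <- us_ids
  mag_dom <- rep(NA_character_, length(us_ids)); names(mag_dom) <- us_ids
  prof <- matrix(0, length(us_ids) + length(bg_ids), n_samp,
                 dimnames = list(c(us_ids, bg_ids), samples$sample_id))
  for (id in us_ids) {
    co <- cohort_of[[id]]
    if (!is.na(co)) {
      base <- cohort_base[[co]]
      lab <- label_of_cohort[[co]]
      mag_dom[[id]] <- dominant[[co]]
    } else {
      lab <- sample(labels, 1, prob = c(0.3, 0.2, 0.15, 0.15, 0.2))
      dom <- pick_site(lab)
      base <- base_profile(dom)
      mag_dom[[id]] <- dom
    }
    mag_label[[id]] <- lab
    p <- base * .lnorm_noise(n_samp, config$abundance_noise_cv)
    p[pref_mask(lab)] <- p[pref_mask(lab)] * config$enrichment_effect
    prof[id, ] <- p
  }
  for (id in bg_ids)    # background community: most of the read mass, so
                        # ultra-small taxa stay a minority of the community
    prof[id, ] <- stats::rlnorm(n_samp, meanlog = log(50), sdlog = 0.6)
  depths <- round(stats::runif(n_samp, config$library_size_range[1],
                               config$library_size_range[2]))
  coverage <- vapply(seq_len(n_samp), function(j)
    stats::rmultinom(1, depths[j], prof[, j])[, 1],
    integer(nrow(prof)))
  dimnames(coverage) <- dimnames(prof)
  cov_truth <- data.frame(
    mag_id = rownames(prof),
    cohort = c(unname(cohort_of), rep(NA_character_, length(bg_ids))),
    enrichment_label = c(unname(mag_label),
                         rep("neutral", length(bg_ids))),
    dominant_site = c(unname(mag_dom), rep(NA_character_, length(bg_ids))))
  list(coverage = coverage, truth = cov_truth)
}

#' Generate the gene table and transcript count matrix
#'
#' Transcriptome samples are labelled oxic/dysoxic (2 + 4 by default).
#' Genes get log-normal lengths (~900 bp), COG categories (ultra-small MAGs
#' mostly unannotated, matching the very high unannotated expression share
#' of these lineages), occasional gene names, and annotation flags. Counts
#' are negative binomial around means built from a per-gene baseline, a
#' per-MAG oxic:dysoxic activity ratio tied to the MAG's enrichment label,
#' and a per-COG-category oxic:dysoxic effect ratio; a small fraction of
#' genes is forced condition-exclusive. The effective (mass-weighted)
#' planted ratios actually realized per MAG and per category are returned
#' as ground truth for recovery checks.
#'
#' @param config a [simulationConfig()].
#' @param mags,truth from [generateMags()]; `cov_truth` from
#'   [generateCoverage()] supplies enrichment labels.
#' @param cov_truth truth table from [generateCoverage()].
#' @return list: `genes`, `counts` (gene x sample), `library_sizes`,
#'   `condition`, `truth_mag_fold` (`mag_id`, `true_fold`),
#'   `truth_category` (`cog_category`, `true_ratio`, `effective_ratio`).
#' @export
generateTranscripts <- function(config, mags, truth, cov_truth) {
  .stage_seed(config, 4L)
  n_t <- config$n_transcriptome_samples
  condition <- c(rep("oxic", config$n_oxic_transcriptomes),
                 rep("dysoxic", n_t - config$n_oxic_transcriptomes))
  sample_ids <- sprintf("t%02d_%s", seq_len(n_t), substr(condition, 1, 3))
  n_genes_mag <- sample(seq(config$genes_per_mag_range[1],
                            config$genes_per_mag_range[2]),
                        nrow(mags), replace = TRUE)
  gene_mag <- rep(mags$mag_id, n_genes_mag)
  n_genes <- length(gene_mag)
  us <- isUltraSmall(mags$group[match(gene_mag, mags$mag_id)])
  cat_raw <- sample(.COG_CATEGORIES, n_genes, replace = TRUE)
  unann <- stats::runif(n_genes) < ifelse(us, 0.84, 0.25)
  cat_raw[unann] <- NA
  genes <- data.frame(
    gene_id = sprintf("g%06d", seq_len(n_genes)),
    mag_id = gene_mag,
    length = pmax(150, round(stats::rlnorm(n_genes, log(900), 0.35))),
    cog_category = cat_raw,
    gene_name = ifelse(stats::runif(n_genes) < 0.04,
                       sample(.GENE_NAMES, n_genes, replace = TRUE),
                       NA_character_),
    signal_peptide = stats::runif(n_genes) < 0.08,
    cell_division_flag = stats::runif(n_genes) < 0.02,
    pili_flag = stats::runif(n_genes) < 0.03,
    antioxidant_flag = stats::runif(n_genes) < 0.01)
  # planted per-MAG oxic:dysoxic activity ratios from enrichment labels
  lab <- cov_truth$enrichment_label[match(mags$mag_id, cov_truth$mag_id)]
  mfold <- config$mag_activity_fold
  spread <- if (mfold > 1) 0.4 else 0
  mag_ratio <- exp(stats::rnorm(nrow(mags), 0, spread / 2))
  mag_ratio[lab == "oxic"] <- exp(stats::rnorm(sum(lab == "oxic"),
                                               log(mfold), spread))
  mag_ratio[lab == "dysoxic"] <- exp(stats::rnorm(sum(lab == "dysoxic"),
                                                  -log(mfold), spread))
  names(mag_ratio) <- mags$mag_id
  cat_ratio <- stats::setNames(
    exp(stats::runif(length(.COG_CATEGORIES),
                     log(config$category_effect_range[1]),
                     log(config$category_effect_range[2]))),
    .COG_CATEGORIES)
  base <- stats::rlnorm(n_genes, log(6), 1)
  g_cat <- genes$cog_category
  g_catmult <- ifelse(is.na(g_cat), 1, cat_ratio[g_cat])
  g_magmult <- mag_ratio[genes$mag_id]
  mu_dys <- base
  mu_oxi <- base * g_catmult * g_magmult
  # force ~2% of genes exclusive to each condition
  excl_oxi <- stats::runif(n_genes) < 0.02
  excl_dys <- !excl_oxi & stats::runif(n_genes) < 0.02
  mu_dys[excl_oxi] <- 0
  mu_oxi[excl_dys] <- 0
  depth_f <- stats::runif(n_t, 0.7, 1.3)
  counts <- vapply(seq_len(n_t), function(j) {
    mu <- (if (condition[j] == "oxic") mu_oxi else mu_dys) * depth_f[j]
    as.numeric(stats::rnbinom(n_genes, mu = mu,
                              size = 1 / config$nb_dispersion))
  }, numeric(n_genes))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, sample_ids)
  library_sizes <- round(colSums(counts) * stats::runif(n_t, 1.05, 1.15))
  # effective planted ratios: the expectation of what modified-TPM based
  # estimates can see. Length weights (1000/len) match the per-kilobase
  # term; the community factor accounts for library-size normalization
  # (modified-TPM is relative to total community output, which itself
  # differs between conditions).
  w <- 1000 / genes$length
  community <- sum(mu_oxi) / sum(mu_dys)
  eff_mag <- vapply(split(seq_len(n_genes), genes$mag_id), function(i)
    sum(mu_oxi[i] * w[i]) / sum(mu_dys[i] * w[i]), numeric(1)) / community
  ann <- !is.na(g_cat)
  eff_cat <- vapply(split(which(ann), g_cat[ann]), function(i)
    sum(mu_oxi[i] * w[i]) / sum(mu_dys[i] * w[i]), numeric(1)) / community
  list(genes = genes, counts = counts, library_sizes = library_sizes,
       condition = condition,
       truth_mag_fold = data.frame(mag_id = names(eff_mag),
                                   true_fold = unname(eff_mag)),
       truth_category = data.frame(cog_category = names(eff_cat),
                                   true_ratio = unname(cat_ratio[names(eff_cat)]),
                                   effective_ratio = unname(eff_cat)))
}

#' Generate synthetic protein alignment hit tables with known AAI
#'
#' For each planted genome pair, reciprocal one-to-one best hits with
#' identities ~ N(true AAI, `aai_sd`), plus decoy hits violating the 30%
#' identity or 70% coverage filter (low identity, or high identity over a
#' short alignment) that a correct filter must discard.
#'
#' @param config a [simulationConfig()]; pairs come from `config$aai_pairs`.
#' @return `data.frame` of hit rows (blast outfmt-6-like schema).
#' @export
generateProteinHits <- function(config) {
  .stage_seed(config, 5L)
  out <- lapply(seq_len(nrow(config$aai_pairs)), function(k) {
    pr <- config$aai_pairs[k, ]
    n <- pr$n_pairs
    qlen <- round(stats::rlnorm(n, log(300), 0.25))
    slen <- round(qlen * stats::runif(n, 0.9, 1.1))
    ident <- pmin(100, pmax(5, stats::rnorm(n, pr$true_aai, config$aai_sd)))
    alen <- round(0.85 * pmin(qlen, slen))
    qid <- sprintf("%s_p%04d", pr$query_genome, seq_len(n))
    sid <- sprintf("%s_p%04d", pr$subject_genome, seq_len(n))
    bits <- round(ident * alen / 50 + stats::runif(n, 0, 2), 1)
    fwd <- data.frame(query_id = qid, subject_id = sid,
                      query_genome = pr$query_genome,
                      subject_genome = pr$subject_genome,
                      percent_identity = ident, alignment_length = alen,
                      query_length = qlen, subject_length = slen,
                      bitscore = bits)
    rev <- data.frame(query_id = sid, subject_id = qid,
                      query_genome = pr$subject_genome,
                      subject_genome = pr$query_genome,
                      percent_identity = ident, alignment_length = alen,
                      query_length = slen, subject_length = qlen,
                      bitscore = bits)
    nd <- max(5L, round(n * 0.1))
    di <- sample(n, nd)
    low_ident <- data.frame(
      query_id = qid[di], subject_id = sprintf("%s_decoyA%04d",
                                               pr$subject_genome, seq_len(nd)),
      query_genome = pr$query_genome, subject_genome = pr$subject_genome,
      percent_identity = stats::runif(nd, 10, 29.5),
      alignment_length = round(0.85 * pmin(qlen[di], slen[di])),
      query_length = qlen[di], subject_length = slen[di],
      bitscore = round(stats::runif(nd, 5, 20), 1))
    short_aln <- data.frame(
      query_id = qid[di], subject_id = sprintf("%s_decoyB%04d",
                                               pr$subject_genome, seq_len(nd)),
      query_genome = pr$query_genome, subject_genome = pr$subject_genome,
      percent_identity = stats::runif(nd, 80, 95),
      alignment_length = round(0.4 * pmin(qlen[di], slen[di])),
      query_length = qlen[di], subject_length = slen[di],
      bitscore = round(stats::runif(nd, 5, 20), 1))
    rbind(fwd, rev, low_ident, short_aln)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the full synthetic-community generator
#'
#' @param config a [simulationConfig()] (or a seed, for defaults).
#' @return list of class `"usmag_simulation"` with `config`, `samples`,
#'   `mags`, `scg`, `coverage`, `genes`, `transcripts` (counts,
#'   library_sizes, condition) and `truth` (per-MAG table plus
#'   `mag_fold` and `category` transcription truths).
#' @export
simulateCommunity <- function(config = simulationConfig()) {
  if (is.numeric(config)) config <- simulationConfig(seed = config)
  stopifnot(inherits(config, "usmag_sim_config"))
  samples <- generateSamples(config)
  gm <- generateMags(config)
  cov <- generateCoverage(config, samples, gm$mags, gm$truth)
  tr <- generateTranscripts(config, gm$mags, gm$truth, cov$truth)
  hits <- generateProteinHits(config)
  truth <- merge(gm$truth, cov$truth, by = "mag_id", sort = TRUE)
  structure(list(
    config = config, samples = samples, mags = gm$mags, scg = gm$scg,
    coverage = cov$coverage,
    genes = tr$genes,
    transcripts = list(counts = tr$counts,
                       library_sizes = tr$library_sizes,
                       condition = tr$condition),
    hits = hits,
    truth = list(mags = truth, mag_fold = tr$truth_mag_fold,
                 category = tr$truth_category)),
    class = "usmag_simulation")
}

#' Write a simulation to tab-separated files
#'
#' Writes samples.tsv, mags.tsv, scg.tsv, coverage.tsv, genes.tsv,
#' transcripts.tsv, libsizes.tsv, hits.tsv, truth_mags.tsv,
#' truth_mag_fold.tsv and truth_category.tsv (UTF-8, header row, '.'
#' decimal separator).
#'
#' @param sim result of [simulateCommunity()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(inherits(sim, "usmag_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE) {
    if (rn) x <- data.frame(id = rownames(x), x, check.names = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    f
  }
  files <- c(
    wt(sim$samples, "samples.tsv"),
    wt(sim$mags, "mags.tsv"),
    wt(sim$scg, "scg.tsv"),
    wt(sim$coverage, "coverage.tsv", rn = TRUE),
    wt(sim$genes, "genes.tsv"),
    wt(sim$transcripts$counts, "transcripts.tsv", rn = TRUE),
    wt(data.frame(sample_id = colnames(sim$transcripts$counts),
                  library_size = sim$transcripts$library_sizes,
                  condition = sim$transcripts$condition), "libsizes.tsv"),
    wt(sim$hits, "hits.tsv"),
    wt(sim$truth$mags, "truth_mags.tsv"),
    wt(sim$truth$mag_fold, "truth_mag_fold.tsv"),
    wt(sim$truth$category, "truth_category.tsv"))
  invisible(file.path(dir, files))
}
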