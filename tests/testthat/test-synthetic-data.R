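cfg_small <- simulationConfig(seed = 101, n_ultrasmall_mags = 40,
                              n_background_mags = 20, n_cohorts = 5,
                              cohort_size_range = c(2, 8),
                              genes_per_mag_range = c(30, 60),
                              library_size_range = c(2e4, 1e5))

test_that("configuration validation rejects impossible designs", {
  expect_error(simulationConfig(cohort_size_range = c(10, 2)), "min must be <=")
  expect_error(simulationConfig(n_cohorts = 200, n_ultrasmall_mags = 100),
               "exceeds")
  expect_error(
    generateSamples(simulationConfig(env_ranges = list(DO = c(4, 7.5)))),
    "straddle")
  expect_error(
    generateSamples(simulationConfig(env_ranges = list(DO = c(0.4, 2.9)))),
    "straddle")
})

test_that("the sample design yields sites x wells x fractions rows within ranges", {
  s <- generateSamples(simulationConfig(seed = 42))
  expect_equal(nrow(s), 4 * 2 * 2)
  expect_true(all(s$DO >= 0.37 & s$DO <= 7.5))
  expect_true(all(s$DOC >= 0 & s$DOC <= 26))
  expect_true(all(s$nitrate_N >= 0.45 & s$nitrate_N <= 12.6))
  expect_true(any(s$redox == "oxic") && any(s$redox == "dysoxic"))
  # site-level DO classes are coherent: no site mixes oxic and dysoxic
  expect_true(all(vapply(split(s$DO > 3, s$site),
                         function(x) length(unique(x)) == 1, TRUE)))
  expect_identical(s, generateSamples(simulationConfig(seed = 42)))
})

test_that("MAG generation matches the size model and SCG conventions", {
  gm <- generateMags(simulationConfig(seed = 7))
  us <- gm$truth$ultra_small
  expect_true(all(gm$truth$true_size[us] >= 4e5))
  expect_equal(mean(gm$truth$true_size[us]), 1e6, tolerance = 0.1)
  expect_true(all(gm$truth$true_size[!us] >= 2e6))
  expect_true(all(gm$mags$completeness >= 0.5 & gm$mags$completeness <= 1))
  expect_true(all(gm$mags$contamination >= 0 & gm$mags$contamination <= 0.05))
  # lineage-specific marker sets
  sets <- unique(gm$scg[, c("mag_id", "scg_set")])
  grp <- gm$mags$group[match(sets$mag_id, gm$mags$mag_id)]
  expect_true(all(sets$scg_set[grp == "Patescibacteria"] == "bact43"))
  expect_true(all(sets$scg_set[grp == "Dependentiae"] == "bact51"))
  expect_true(all(sets$scg_set[startsWith(grp, "DPANN")] == "arch38"))
  # SCG-derived completeness tracks the drawn completeness
  m1 <- gm$mags[gm$mags$mag_id == "usmag001", ]
  prof <- gm$scg[gm$scg$mag_id == "usmag001", ]
  cc <- scgCompleteness(setNames(prof$copies, prof$marker_id),
                        prof$scg_set[1])
  expect_lt(abs(cc[["completeness"]] - m1$completeness), 0.25)
})

test_that("estimated genome size recovers the planted truth within 5% median error", {
  gm <- generateMags(simulationConfig(seed = 12))
  us <- gm$truth$ultra_small
  est <- estimateGenomeSize(gm$mags$bin_size[us], gm$mags$completeness[us],
                            gm$mags$contamination[us])
  rel_err <- abs(est - gm$truth$true_size[us]) / gm$truth$true_size[us]
  expect_lte(median(rel_err), 0.05)
})

test_that("coverage counts conserve the drawn per-sample depths", {
  s <- generateSamples(cfg_small)
  gm <- generateMags(cfg_small)
  cov <- generateCoverage(cfg_small, s, gm$mags, gm$truth)
  expect_equal(dim(cov$coverage), c(60L, 16L))
  expect_true(all(colSums(cov$coverage) >= cfg_small$library_size_range[1]))
  expect_true(all(colSums(cov$coverage) <= cfg_small$library_size_range[2]))
  # depths differ across samples (normalization is non-trivial)
  expect_gt(max(colSums(cov$coverage)) / min(colSums(cov$coverage)), 1.2)
  # every ultra-small MAG has exactly one cohort value (possibly none)
  expect_equal(nrow(cov$truth), 60)
  expect_false(anyDuplicated(cov$truth$mag_id) > 0)
})

test_that("zero abundance noise makes within-cohort profiles rank-identical", {
  cfg0 <- simulationConfig(seed = 3, n_ultrasmall_mags = 30,
                           n_background_mags = 5, n_cohorts = 4,
                           cohort_size_range = c(4, 8),
                           abundance_noise_cv = 0)
  s <- generateSamples(cfg0)
  gm <- generateMags(cfg0)
  cov <- generateCoverage(cfg0, s, gm$mags, gm$truth)
  tr <- cov$truth[!is.na(cov$truth$cohort), ]
  co1 <- tr$mag_id[tr$cohort == tr$cohort[1]]
  # expected profiles identical; multinomial sampling noise only, so use
  # the underlying expectation via large depths: check high rank correlation
  rho <- cor(t(cov$coverage[co1, ]), method = "spearman")
  expect_gt(min(rho), 0.9)
})

test_that("cohorts with disjoint dominant sites anti-correlate on average", {
  s <- generateSamples(cfg_small)
  gm <- generateMags(cfg_small)
  cov <- generateCoverage(cfg_small, s, gm$mags, gm$truth)
  tr <- cov$truth[!is.na(cov$truth$cohort), ]
  rel <- relativeAbundance(cov$coverage)
  rho <- cor(t(rel[tr$mag_id, ]), method = "spearman")
  # pairs from different cohorts, different dominant sites, and different
  # preference labels share no planted structure: their expected rank
  # correlation is <= 0 (one's high-abundance site is the other's low)
  diff_all <- outer(tr$cohort, tr$cohort, "!=") &
    outer(tr$dominant_site, tr$dominant_site, "!=") &
    outer(tr$enrichment_label, tr$enrichment_label, "!=")
  vals <- rho[diff_all & upper.tri(rho)]
  expect_gt(length(vals), 10)
  expect_lte(mean(vals), 0)
})

test_that("planted enrichment effects appear as ~4x empirical factors", {
  # isolate the enrichment effect: no site structure (site_effect = 1)
  effs <- replicate(40, NA_real_)
  for (i in seq_along(effs)) {
    cfg <- simulationConfig(seed = 1000 + i, n_ultrasmall_mags = 30,
                            n_background_mags = 10, n_cohorts = 3,
                            cohort_size_range = c(4, 8), site_effect = 1,
                            library_size_range = c(2e5, 2e5))
    s <- generateSamples(cfg)
    gm <- generateMags(cfg)
    cov <- generateCoverage(cfg, s, gm$mags, gm$truth)
    oxic <- s$sample_id[s$DO > 3]
    dys <- setdiff(s$sample_id, oxic)
    rel <- relativeAbundance(cov$coverage)
    ids <- cov$truth$mag_id[cov$truth$enrichment_label == "oxic" &
                              !is.na(cov$truth$cohort)]
    if (!length(ids)) next
    ef <- enrichmentFactors(rel, oxic, dys)
    effs[i] <- mean(ef$factor[ef$taxon_id %in% ids], na.rm = TRUE)
  }
  expect_equal(mean(effs, na.rm = TRUE), 4, tolerance = 0.2)
})

test_that("transcript generation plants conditions, exclusivity and effects", {
  gm <- generateMags(cfg_small)
  s <- generateSamples(cfg_small)
  cov <- generateCoverage(cfg_small, s, gm$mags, gm$truth)
  tx <- generateTranscripts(cfg_small, gm$mags, gm$truth, cov$truth)
  expect_equal(table(tx$condition)[["oxic"]], 2)
  expect_equal(table(tx$condition)[["dysoxic"]], 4)
  expect_true(all(tx$library_sizes >= colSums(tx$counts)))
  expect_true(all(tx$genes$length > 0))
  # a gene with zero counts in all oxic samples is dysoxic-exclusive
  tpm <- modifiedTpm(tx$counts, tx$genes$length, tx$library_sizes)
  ex <- exclusiveDetection(tpm, factor(tx$condition,
                                       levels = c("oxic", "dysoxic")))
  oxic_cols <- tx$condition == "oxic"
  zero_oxic <- rownames(tx$counts)[rowSums(tx$counts[, oxic_cols]) == 0 &
                                     rowSums(tx$counts) > 0]
  expect_setequal(ex$exclusive_dysoxic, zero_oxic)
})

test_that("flat planted effects give ~50/50 category condition proportions", {
  cfg_flat <- simulationConfig(seed = 77, n_ultrasmall_mags = 40,
                               n_background_mags = 20, n_cohorts = 5,
                               cohort_size_range = c(2, 8),
                               genes_per_mag_range = c(80, 120),
                               category_effect_range = c(1, 1),
                               mag_activity_fold = 1)
  s <- generateSamples(cfg_flat)
  gm <- generateMags(cfg_flat)
  cov <- generateCoverage(cfg_flat, s, gm$mags, gm$truth)
  tx <- generateTranscripts(cfg_flat, gm$mags, gm$truth, cov$truth)
  tpm <- modifiedTpm(tx$counts, tx$genes$length, tx$library_sizes)
  cp <- categoryConditionProportion(tpm, tx$genes,
                                    factor(tx$condition,
                                           levels = c("oxic", "dysoxic")))
  expect_equal(mean(cp$percent_oxic), 50, tolerance = 0.1)
  expect_true(all(abs(cp$percent_oxic - 50) < 15))
})

test_that("protein hit tables carry the planted AAI and filterable decoys", {
  cfg <- simulationConfig(seed = 9, aai_sd = 0,
                          aai_pairs = data.frame(
                            query_genome = "qa", subject_genome = "rb",
                            true_aai = 100, n_pairs = 50))
  h <- generateProteinHits(cfg)
  expect_equal(aai(h, "qa", "rb")$aai, 100)
  # decoys: low identity and short-alignment rows are all filtered out
  decoys <- grepl("decoy", h$subject_id)
  expect_gt(sum(decoys), 0)
  f <- filterHits(h)
  expect_false(any(grepl("decoy", f$subject_id)))
  # default pairs: planted 55 recovered within +/- 2 over 200 hit pairs
  h2 <- generateProteinHits(simulationConfig(seed = 10))
  expect_equal(aai(h2, "qgen1", "ref1")$aai, 55, tolerance = 2 / 55)
})

test_that("the same seed reproduces the whole simulation bit-identically", {
  s1 <- simulateCommunity(cfg_small)
  s2 <- simulateCommunity(cfg_small)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$coverage, s2$coverage)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$hits, s2$hits)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimulation(s1, d1); writeSimulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
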