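test_that("normalizeCounts scales every sample to the deepest sample's total", {
  m <- toy_matrix(cbind(c(95, 5), c(45, 5)))   # totals 100 and 50
  nm <- normalizeCounts(m)
  expect_equal(unname(colSums(nm)), c(100, 100))
  expect_equal(nm["t2", "s2"], 10)             # 5 reads scaled by 100/50
  # equal totals: unchanged; single sample: unchanged
  eq <- toy_matrix(cbind(c(3, 7), c(6, 4)))
  expect_equal(normalizeCounts(eq), eq)
  one <- toy_matrix(cbind(c(3, 7)))
  expect_equal(normalizeCounts(one), one)
  # zero-total column left zero, with a warning
  z <- toy_matrix(cbind(c(2, 2), c(0, 0)))
  expect_warning(nz <- normalizeCounts(z), "zero")
  expect_equal(unname(nz[, 2]), c(0, 0))
})

test_that("normalization preserves within-sample proportions exactly", {
  set.seed(11)
  for (i in 1:20) {
    m <- toy_matrix(matrix(rpois(60, 40), 10, 6))
    expect_equal(relativeAbundance(normalizeCounts(m)),
                 relativeAbundance(m))
  }
})

test_that("relative abundances sum to one per sample (zero samples stay zero)", {
  expect_equal(unname(relativeAbundance(toy_matrix(cbind(c(2, 2))))[, 1]),
               c(0.5, 0.5))
  z <- toy_matrix(cbind(c(0, 0), c(1, 3)))
  expect_equal(unname(relativeAbundance(z)[, 1]), c(0, 0))
  set.seed(7)
  for (i in 1:100) {
    m <- toy_matrix(matrix(runif(40), 8, 5))
    expect_equal(unname(colSums(relativeAbundance(m))), rep(1, 5))
  }
})

test_that("AbundanceExperiment validates stage and non-negativity", {
  m <- toy_matrix(cbind(c(5, 5), c(2, 8)))
  ae <- AbundanceExperiment(m)
  expect_equal(abundanceStage(ae), "counts")
  rel <- relativeAbundance(normalizeCounts(ae))
  expect_s4_class(rel, "AbundanceExperiment")
  expect_equal(abundanceStage(rel), "relative")
  expect_error(AbundanceExperiment(m - 3), "non-negative")
  expect_error(AbundanceExperiment(m, stage = "relative"), "sum to 1")
  expect_error(normalizeCounts(rel), "counts.*stage|stage")
})

test_that("enrichment factors classify enriched, exclusive, neutral and absent taxa", {
  rel <- toy_matrix(rbind(c(0.02, 0.02, 0.01, 0.01),
                          c(0.01, 0.01, 0.01, 0.01),
                          c(0.03, 0.05, 0, 0),
                          c(0, 0, 0, 0)),
                    taxa = c("up", "flat", "exc", "none"))
  ef <- enrichmentFactors(rel, c("s1", "s2"), c("s3", "s4"))
  expect_equal(ef$factor[ef$taxon_id == "up"], 2)
  expect_equal(ef$class[ef$taxon_id == "up"], "enriched-A")
  expect_equal(ef$factor[ef$taxon_id == "flat"], 1)
  expect_equal(ef$class[ef$taxon_id == "flat"], "neutral")
  expect_equal(ef$factor[ef$taxon_id == "exc"], Inf)
  expect_equal(ef$class[ef$taxon_id == "exc"], "exclusive-A")
  expect_equal(ef$class[ef$taxon_id == "none"], "absent")
  expect_error(enrichmentFactors(rel, c("s1"), c("s1", "s3")), "disjoint")
})

test_that("enrichment factors invert exactly when the groups are swapped", {
  set.seed(5)
  rel <- relativeAbundance(toy_matrix(matrix(runif(24, 0.1, 1), 4, 6)))
  ab <- enrichmentFactors(rel, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  ba <- enrichmentFactors(rel, c("s4", "s5", "s6"), c("s1", "s2", "s3"))
  expect_equal(ab$factor * ba$factor, rep(1, 4))
})

test_that("prevalence uses the ceiling of the sample fraction", {
  m <- matrix(0, 2, 81, dimnames = list(c("a", "b"), paste0("s", 1:81)))
  m["a", 1:41] <- 1   # present in exactly ceil(0.5 * 81) = 41 samples
  m["b", 1:40] <- 1
  expect_equal(prevalentTaxa(m, 0.5), "a")
  m["b", ] <- 1
  expect_true("b" %in% prevalentTaxa(m, 1))
  m["b", 81] <- 0
  expect_false("b" %in% prevalentTaxa(m, 1))
})

test_that("shared taxa partition and percentages come from per-group presence", {
  m <- toy_matrix(rbind(c(1, 0), c(1, 1), c(0, 2)),
                  taxa = c("onlyA", "both", "onlyB"))
  st <- sharedTaxa(m, "s1", "s2")
  expect_equal(unname(st$counts), c(1, 1, 1))
  expect_equal(st$taxa$shared, "both")
  ident <- toy_matrix(rbind(c(1, 1), c(2, 2)))
  st2 <- sharedTaxa(ident, "s1", "s2")
  expect_equal(unname(st2$counts), c(0, 2, 0))
  disj <- toy_matrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(sharedTaxa(disj, "s1", "s2")$counts), c(1, 0, 1))
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  x <- setNames(c(10L, 5L, 0L, 25L), paste0("t", 1:4))
  full <- rarefyCounts(x, sum(x), seed = 1)
  expect_equal(full, x)                      # depth = total: unchanged
  r <- rarefyCounts(x, 12, seed = 2)
  expect_equal(sum(r), 12)
  expect_true(all(r <= x))
  expect_error(rarefyCounts(x, 41), "exceeds")
})

test_that("richness and Shannon behave on degenerate and simple samples", {
  m <- toy_matrix(cbind(c(4, 0, 1), c(0, 9, 0)))
  expect_equal(unname(richness(m)), c(2, 1))
  expect_equal(unname(shannonIndex(m))[2], 0)  # single-taxon sample
  p <- c(0.5, 0.5)
  expect_equal(unname(shannonIndex(toy_matrix(cbind(p))))[1], log(2))
})

test_that("Bray-Curtis matches the min-sum formula with defined degenerate cases", {
  same <- toy_matrix(cbind(c(1, 2), c(1, 2)))
  expect_equal(unname(brayCurtis(same)[1, 2]), 0)
  disj <- toy_matrix(cbind(c(1, 0), c(0, 1)))
  expect_equal(unname(brayCurtis(disj)[1, 2]), 1)
  uv <- toy_matrix(cbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(unname(brayCurtis(uv)[1, 2]), 0.5)
  set.seed(3)
  m <- toy_matrix(matrix(rpois(40, 5), 8, 5))
  d <- brayCurtis(m)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  withz <- toy_matrix(cbind(c(0, 0), c(0, 0), c(1, 2)))
  expect_warning(dz <- brayCurtis(withz), "all-zero")
  expect_equal(unname(dz[1, 2]), 0)
  expect_equal(unname(dz[1, 3]), 1)
})

test_that("min-max scaling maps the observed range onto the target interval", {
  do <- c(0.37, 7.5, (0.37 + 7.5) / 2)
  sc <- scaleMinMax(do, 0, 1)
  expect_equal(sc, c(0, 1, 0.5))
  expect_equal(scaleMinMax(sc, 0, 1), sc)      # idempotent on [0,1]
  expect_equal(scaleMinMax(do, 0, 100)[2], 100)
  expect_warning(cz <- scaleMinMax(rep(2, 4), 0, 1), "constant")
  expect_equal(cz, rep(0, 4))
})

test_that("group fraction sums the subset's relative abundance per sample", {
  rel <- relativeAbundance(toy_matrix(rbind(c(1, 2), c(1, 2), c(2, 4)),
                                      taxa = c("u1", "u2", "o1")))
  expect_equal(unname(groupFraction(rel, c("u1", "u2", "o1"))), c(1, 1))
  expect_equal(unname(groupFraction(rel, character(0))), c(0, 0))
  expect_equal(unname(groupFraction(rel, c("u1", "u2"))), c(0.5, 0.5))
})
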