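test_that("modified-TPM evaluates the reads * (1000/len) * (1e6/lib) product", {
  expect_equal(modifiedTpm(1, 1000, 1e6), 1)
  expect_equal(modifiedTpm(10, 500, 2e6), 10)
  expect_equal(modifiedTpm(0, 750, 3e6), 0)
  expect_error(modifiedTpm(1, 0, 1e6), "length")
  expect_error(modifiedTpm(1, 1000, 0), "library")
  # linear in counts; doubling the library halves every value
  expect_equal(modifiedTpm(6, 800, 1e6), 3 * modifiedTpm(2, 800, 1e6))
  expect_equal(modifiedTpm(5, 400, 2e6), modifiedTpm(5, 400, 1e6) / 2)
})

test_that("with 1 kb genes the TPM total reduces to 1e6 * mapped/library", {
  cnt <- toy_matrix(matrix(c(10, 20, 30, 15, 25, 35), 3, 2),
                    taxa = paste0("g", 1:3))
  tpm <- modifiedTpm(cnt, rep(1000, 3), c(1e6, 2e6))
  expect_equal(unname(colSums(tpm)),
               1e6 * c(60 / 1e6, 75 / 2e6))
})

test_that("per-MAG expression totals, genome-size normalization and shares", {
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      mag_id = c("A", "A", "B", "B"),
                      length = rep(1000, 4))
  tpm <- toy_matrix(rbind(c(3, 1), c(3, 1), c(6, 2), c(0, 0)),
                    taxa = genes$gene_id)
  mx <- magExpression(tpm, genes)
  expect_equal(unname(mx$totals["A", ]), c(6, 2))
  # one MAG owning all expression has community share 1
  solo <- magExpression(tpm[1:2, , drop = FALSE], genes[1:2, ])
  expect_equal(unname(solo$share["A", ]), c(1, 1))
  # equal totals, sizes 1 and 2 Mbp: normalized shares 2/3 vs 1/3
  mags <- data.frame(mag_id = c("A", "B"), estimated_size = c(1e6, 2e6))
  tpm_eq <- toy_matrix(rbind(c(3, 3), c(3, 3), c(6, 6), c(0, 0)),
                       taxa = genes$gene_id)
  mn <- magExpression(tpm_eq, genes, mags, normalizeByGenomeSize = TRUE)
  expect_equal(unname(mn$share[, 1]), c(2 / 3, 1 / 3))
  # a silent MAG is reported not detected
  tpm0 <- toy_matrix(rbind(c(3, 1), c(3, 1), c(0, 0), c(0, 0)),
                     taxa = genes$gene_id)
  expect_equal(magExpression(tpm0, genes)$not_detected, "B")
  # orphan genes are excluded with a warning
  expect_warning(magExpression(tpm, genes[1:3, ]), "no MAG")
})

test_that("category condition proportions are complementary percentages", {
  genes <- data.frame(gene_id = paste0("g", 1:3),
                      mag_id = "A", length = 1000,
                      cog_category = c("E", "E", "N"))
  cond <- factor(c("oxic", "oxic", "dysoxic", "dysoxic"),
                 levels = c("oxic", "dysoxic"))
  tpm <- toy_matrix(rbind(c(44, 44, 6, 6), c(44, 44, 6, 6),
                          c(5, 5, 5, 5)), taxa = genes$gene_id,
                    samples = paste0("t", 1:4))
  cp <- categoryConditionProportion(tpm, genes, cond)
  expect_equal(cp$percent_oxic[cp$cog_category == "E"], 88)
  expect_equal(cp$percent_oxic[cp$cog_category == "N"], 50)
  expect_equal(cp$percent_oxic + cp$percent_dysoxic, rep(100, 2))
  # invariant to sample order within conditions
  perm <- c(2, 1, 4, 3)
  cp2 <- categoryConditionProportion(tpm[, perm], genes, cond[perm])
  expect_equal(cp2, cp)
  # zero-expression categories are excluded with a note
  genes3 <- rbind(genes, data.frame(gene_id = "g4", mag_id = "A",
                                    length = 1000, cog_category = "Z"))
  tpm3 <- rbind(tpm, g4 = rep(0, 4))
  cp3 <- categoryConditionProportion(tpm3, genes3, cond)
  expect_false("Z" %in% cp3$cog_category)
  expect_equal(attr(cp3, "excluded_categories"), "Z")
})

test_that("condition-exclusive detection partitions expressed features", {
  cond <- factor(c("oxic", "dysoxic", "dysoxic"),
                 levels = c("oxic", "dysoxic"))
  tpm <- toy_matrix(rbind(c(1, 0, 0),   # oxic-exclusive
                          c(0, 2, 1),   # dysoxic-exclusive
                          c(1, 1, 0),   # shared
                          c(0, 0, 0)),  # silent: in no set
                    taxa = paste0("g", 1:4), samples = paste0("t", 1:3))
  ex <- exclusiveDetection(tpm, cond)
  expect_equal(ex$exclusive_oxic, "g1")
  expect_equal(ex$exclusive_dysoxic, "g2")
  expect_equal(ex$shared, "g3")
  expect_equal(unname(ex$percent), c(1 / 3, 1 / 3) * 100)
  # larger constructed split: exact counts
  set.seed(9)
  m <- toy_matrix(rbind(matrix(c(rep(1, 4 * 1), rep(0, 4 * 2)), 4, 3),
                        matrix(c(rep(0, 3), rep(1, 6)), 3, 3),
                        matrix(1, 3, 3)),
                  taxa = paste0("h", 1:10), samples = paste0("t", 1:3))
  ex2 <- exclusiveDetection(m, cond)
  expect_equal(unname(ex2$counts), c(4, 3, 3))
})

test_that("fold change is the ratio of condition means with an infinity flag", {
  cond <- factor(c("oxic", "oxic", "dysoxic", "dysoxic"),
                 levels = c("oxic", "dysoxic"))
  totals <- toy_matrix(rbind(c(4, 4, 1, 1), c(2, 2, 2, 2),
                             c(3, 1, 0, 0), c(0, 0, 0, 0)),
                       taxa = c("up", "flat", "excl", "silent"),
                       samples = paste0("t", 1:4))
  fc <- conditionFoldChange(totals, cond)
  expect_equal(fc$fold_change[fc$mag_id == "up"], 4)
  expect_equal(fc$fold_change[fc$mag_id == "flat"], 1)
  expect_equal(fc$fold_change[fc$mag_id == "excl"], Inf)
  expect_false("silent" %in% fc$mag_id)
})

test_that("z-scaling centers and standardizes the chosen dimension", {
  m <- toy_matrix(rbind(1:3, c(5, 5, 5)))
  expect_warning(zr <- zscoreScale(m, "row"), "constant")
  expect_equal(unname(zr[1, ]), c(-1, 0, 1))
  expect_equal(unname(zr[2, ]), c(0, 0, 0))
  set.seed(4)
  mm <- matrix(rnorm(24), 4, 6)
  zm <- zscoreScale(mm, "row")
  expect_equal(unname(rowMeans(zm)), rep(0, 4))
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 4))
  zc <- zscoreScale(mm, "column")
  expect_equal(unname(colMeans(zc)), rep(0, 6))
  zrc <- zscoreScale(mm, "row-then-column")
  expect_equal(unname(colMeans(zrc)), rep(0, 6))
})

test_that("unannotated expression share splits ultra-small from other MAGs", {
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      mag_id = c("u1", "u1", "b1", "b1"),
                      length = 1000,
                      cog_category = c("E", NA, NA, NA))
  mags <- data.frame(mag_id = c("u1", "b1"),
                     group = c("Patescibacteria", "other"))
  tpm <- toy_matrix(rbind(c(5, 5), c(5, 5), c(7, 7), c(0, 0)),
                    taxa = genes$gene_id)
  af <- annotatedFraction(tpm, genes, mags)
  expect_equal(unname(af["ultra_small", ]), c(50, 50))
  expect_equal(unname(af["other", ]), c(100, 100))
  all_ann <- annotatedFraction(
    tpm[1, , drop = FALSE], genes[1, , drop = FALSE])
  expect_equal(unname(all_ann["all", ]), c(0, 0))
})

test_that("top expressed genes rank by total with lexicographic tie-break", {
  genes <- data.frame(gene_id = paste0("g", 1:5),
                      mag_id = "A", length = 1000,
                      gene_name = c("rpoB", "cspA", NA, "gyrA", "recA"))
  tpm <- toy_matrix(rbind(c(5, 3), c(9, 1), c(50, 50), c(6, 4), c(4, 4)),
                    taxa = genes$gene_id)
  top <- topExpressed(tpm, genes, k = 10, namedOnly = TRUE)
  expect_equal(top$gene_id, c("g2", "g4", "g1", "g5"))  # g2/g4 tie -> id order
  expect_true(top$cold_shock_flag[top$gene_name == "cspA"])
  expect_equal(nrow(topExpressed(tpm, genes, k = 2)), 2)
  all5 <- topExpressed(tpm, genes, k = 99, namedOnly = FALSE)
  expect_equal(all5$gene_id[1], "g3")
})
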