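#' @include AllClasses.R AllGenerics.R
NULL

.as_abundance_matrix <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
}

#' @describeIn normalizeCounts matrix method: every sample column is scaled
#'   by `max(column totals) / (its column total)`, so all column totals
#'   equal the largest sample's mapped-read total. Within-sample proportions
#'   are preserved exactly. All-zero columns are left untouched with a
#'   warning.
#' @export
setMethod("normalizeCounts", "matrix", function(x, ...) {
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- colSums(x)
  if (all(tot == 0)) {
    warning("all sample totals are zero; matrix returned unchanged")
    return(x)
  }
  if (any(tot == 0))
    warning("sample(s) with zero total left all-zero: ",
            paste(colnames(x)[tot == 0], collapse = ", "))
  f <- ifelse(tot > 0, max(tot) / tot, 1)
  sweep(x, 2, f, `*`)
})

#' @describeIn normalizeCounts AbundanceExperiment method; requires the
#'   `"counts"` stage and returns a `"normalized"`-stage object.
#' @export
setMethod("normalizeCounts", "AbundanceExperiment", function(x, ...) {
  if (abundanceStage(x) != "counts")
    stop("normalizeCounts expects the 'counts' stage, got '",
         abundanceStage(x), "'")
  m <- normalizeCounts(assay(x))
  out <- AbundanceExperiment(m, colData(x), stage = "normalized")
  metadata(out) <- metadata(x)
  out
})

#' @describeIn relativeAbundance matrix method: each column divided by its
#'   total; all-zero columns stay zero.
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  if (any(x < 0)) stop("values must be non-negative")
  tot <- colSums(x)
  sweep(x, 2, ifelse(tot > 0, tot, 1), `/`)
})

#' @describeIn relativeAbundance AbundanceExperiment method; returns a
#'   `"relative"`-stage object.
#' @export
setMethod("relativeAbundance", "AbundanceExperiment", function(x, ...) {
  m <- relativeAbundance(assay(x))
  out <- AbundanceExperiment(m, colData(x), stage = "relative")
  metadata(out) <- metadata(x)
  out
})

#' Enrichment factors and classes between two sample groups
#'
#' For each taxon the enrichment factor is the ratio of its mean relative
#' abundance in group A over group B (e.g. oxic over anoxic-to-dysoxic, or
#' planktonic over sediment-enriched). A taxon absent from B but present in
#' A is exclusive to A (factor `Inf`); factors inside the neutral band
#' `[1/neutralBand, neutralBand]` are classed neutral.
#'
#' @param rel relative-abundance matrix (taxa x samples) or
#'   `AbundanceExperiment`.
#' @param groupA,groupB disjoint, non-empty character vectors of sample ids
#'   (or column indices).
#' @param grouping label describing the contrast (recorded in the output).
#' @param neutralBand half-width of the multiplicative neutral band
#'   (default 1.05); set to 1 to class any factor != 1 as enriched.
#' @return `data.frame`: `taxon_id`, `mean_a`, `mean_b`, `factor`, `class`
#'   (enriched-A/enriched-B/exclusive-A/exclusive-B/neutral/absent),
#'   `grouping`.
#' @examples
#' m <- matrix(c(4, 1, 0, 2, 2, 1), 3, 2,
#'             dimnames = list(c("t1", "t2", "t3"), c("a1", "b1")))
#' enrichmentFactors(relativeAbundance(m), "a1", "b1")
#' @export
enrichmentFactors <- function(rel, groupA, groupB,
                              grouping = "A-vs-B", neutralBand = 1.05) {
  m <- .as_abundance_matrix(rel)
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  stopifnot(neutralBand >= 1)
  ma <- rowMeans(m[, groupA, drop = FALSE])
  mb <- rowMeans(m[, groupB, drop = FALSE])
  factor <- ifelse(ma == 0 & mb == 0, NA_real_, ma / mb)
  cls <- rep("neutral", nrow(m))
  cls[ma == 0 & mb == 0] <- "absent"
  cls[ma > 0 & mb == 0] <- "exclusive-A"
  cls[ma == 0 & mb > 0] <- "exclusive-B"
  finite <- ma > 0 & mb > 0
  cls[finite & factor > neutralBand] <- "enriched-A"
  cls[finite & factor < 1 / neutralBand] <- "enriched-B"
  data.frame(taxon_id = rownames(m), mean_a = ma, mean_b = mb,
             factor = factor, class = cls, grouping = grouping,
             row.names = NULL)
}

#' Taxa present in at least a given fraction of samples
#'
#' A taxon is kept when it has a value above `floor` in at least
#' `ceiling(minFraction * n_samples)` samples.
#'
#' @param x abundance matrix or `AbundanceExperiment`.
#' @param minFraction required sample fraction in (0, 1].
#' @param floor presence threshold; presence is value > `floor` (default 0,
#'   i.e. any positive value).
#' @return character vector of taxon ids.
#' @export
prevalentTaxa <- function(x, minFraction = 0.5, floor = 0) {
  stopifnot(minFraction > 0, minFraction <= 1)
  m <- .as_abundance_matrix(x)
  need <- ceiling(minFraction * ncol(m))
  rownames(m)[rowSums(m > floor) >= need]
}

#' Taxa shared between (and exclusive to) two sample fractions
#'
#' Presence in a fraction means a positive value in at least one of its
#' samples. Percentages are of taxa present in at least one of the two
#' fractions (taxa absent from both are ignored), together with the share
#' of each fraction's total abundance carried by each partition.
#'
#' @param x abundance matrix or `AbundanceExperiment`.
#' @param fractionA,fractionB disjoint, non-empty sample id vectors.
#' @param floor presence threshold (value > floor), default 0.
#' @return list with `counts` (named: only_a, shared, only_b),
#'   `taxa` (character vectors per partition), and `abundance_share`
#'   (per-fraction fraction of total abundance in each partition).
#' @export
sharedTaxa <- function(x, fractionA, fractionB, floor = 0) {
  if (!length(fractionA) || !length(fractionB))
    stop("fractions must be non-empty")
  if (length(intersect(fractionA, fractionB)))
    stop("fractions must be disjoint")
  m <- .as_abundance_matrix(x)
  inA <- rowSums(m[, fractionA, drop = FALSE] > floor) > 0
  inB <- rowSums(m[, fractionB, drop = FALSE] > floor) > 0
  taxa <- list(only_a = rownames(m)[inA & !inB],
               shared = rownames(m)[inA & inB],
               only_b = rownames(m)[!inA & inB])
  sumA <- sum(m[, fractionA, drop = FALSE])
  sumB <- sum(m[, fractionB, drop = FALSE])
  share <- vapply(taxa, function(ids) {
    c(fraction_a = if (sumA > 0)
        sum(m[ids, fractionA, drop = FALSE]) / sumA else 0,
      fraction_b = if (sumB > 0)
        sum(m[ids, fractionB, drop = FALSE]) / sumB else 0)
  }, numeric(2))
  list(counts = lengths(taxa), taxa = taxa, abundance_share = t(share))
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement (seeded), so the rarefied counts sum
#' exactly to `depth`.
#'
#' @param counts non-negative integer vector (one sample).
#' @param depth target depth, `<= sum(counts)`.
#' @param seed optional integer seed for the draw.
#' @return integer vector of the same length and names, summing to `depth`.
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
  counts <- round(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (depth > sum(counts))
    stop("rarefaction depth (", depth, ") exceeds sample total (",
         sum(counts), ")")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(sum(counts), depth)
  pool <- rep.int(seq_along(counts), counts)
  out <- tabulate(pool[idx], nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Observed richness per sample
#' @param x abundance matrix or `AbundanceExperiment`.
#' @param floor presence threshold (value > floor).
#' @return integer vector, one value per sample.
#' @export
richness <- function(x, floor = 0) {
  m <- .as_abundance_matrix(x)
  colSums(m > floor)
}

#' Shannon diversity per sample (natural log)
#' @param x abundance matrix or `AbundanceExperiment` (counts or relative).
#' @return numeric vector of H = -sum p log p in nats, one per sample.
#' @export
shannonIndex <- function(x) {
  m <- .as_abundance_matrix(x)
  vegan::diversity(t(m), index = "shannon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))`. Pairs of
#' all-zero samples are defined to have distance 0 (with a warning).
#'
#' @param x abundance matrix (taxa x samples) or `AbundanceExperiment`.
#' @return symmetric `matrix` of dissimilarities in \[0, 1\], zero diagonal.
#' @export
brayCurtis <- function(x) {
  m <- .as_abundance_matrix(x)
  if (any(m < 0)) stop("values must be non-negative")
  empty <- colSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (any(empty)) {
    warning("all-zero sample(s); their pairwise distances set to 0: ",
            paste(colnames(m)[empty], collapse = ", "))
    d[empty, ] <- 1
    d[, empty] <- 1
    d[empty, empty] <- 0
  }
  diag(d) <- 0
  d
}

#' Min-max scaling onto a target interval
#'
#' Affine map of the observed `[min, max]` onto `[lo, hi]`; used to put
#' chemistry parameters on a common 0-1 (or 0-100) scale.
#'
#' @param values numeric vector.
#' @param lo,hi target interval (default \[0, 1\]).
#' @return scaled numeric vector; a constant vector maps to `lo` with a
#'   warning.
#' @export
scaleMinMax <- function(values, lo = 0, hi = 1) {
  stopifnot(hi > lo)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant vector; all values mapped to lo")
    return(rep(lo, length(values)))
  }
  lo + (values - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Per-sample abundance share of a taxon subset
#'
#' E.g. the proportion of each community contributed by ultra-small
#' prokaryotes.
#'
#' @param rel relative-abundance matrix or `AbundanceExperiment`.
#' @param taxa character vector, a subset of the row ids.
#' @return numeric vector: per sample, the summed relative abundance of
#'   `taxa`.
#' @export
groupFraction <- function(rel, taxa) {
  m <- .as_abundance_matrix(rel)
  if (!all(taxa %in% rownames(m)))
    stop("taxa not in matrix: ",
         paste(utils::head(setdiff(taxa, rownames(m))), collapse = ", "))
  colSums(m[taxa, , drop = FALSE])
}

#' Expected richness after rarefaction (closed form)
#'
#' Hypergeometric expectation `sum_i (1 - choose(N - N_i, d)/choose(N, d))`
#' for subsampling `d` of `N` reads; the analytic counterpart of repeated
#' [rarefyCounts()] draws.
#'
#' @param counts non-negative integer vector.
#' @param depth subsample depth.
#' @return expected number of taxa observed.
#' @export
expectedRarefiedRichness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N) stop("depth exceeds total")
  # lchoose for numerical stability at large N
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}
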