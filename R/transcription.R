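#' @include AllClasses.R
NULL

#' Modified-TPM transcript normalization
#'
#' `reads * (1000 / gene length) * (1e6 / library size)`: reads per kilobase
#' of gene per million reads of library, using the sample's library size
#' rather than a per-sample sum of rates.
#'
#' @param counts mapped read count(s): scalar, vector, or gene x sample
#'   matrix.
#' @param geneLength gene length(s) in bp (> 0), recycled along rows for a
#'   matrix.
#' @param librarySize library size(s) in reads (> 0); for a matrix, one
#'   value per column.
#' @return modified-TPM values with the shape of `counts`.
#' @examples
#' modifiedTpm(1, 1000, 1e6)        # 1
#' modifiedTpm(10, 500, 2e6)        # 10
#' @export
modifiedTpm <- function(counts, geneLength, librarySize) {
  if (any(geneLength <= 0)) stop("gene length must be positive")
  if (any(librarySize <= 0)) stop("library size must be positive")
  if (is.matrix(counts)) {
    stopifnot(length(geneLength) %in% c(1L, nrow(counts)),
              length(librarySize) %in% c(1L, ncol(counts)))
    out <- counts * (1000 / geneLength)
    sweep(out, 2, 1e6 / librarySize, `*`)
  } else {
    counts * (1000 / geneLength) * (1e6 / librarySize)
  }
}

#' Modified-TPM matrix of a TranscriptExperiment
#' @param te a [TranscriptExperiment-class].
#' @return numeric matrix, genes x samples.
#' @export
transcriptTpm <- function(te) {
  stopifnot(is(te, "TranscriptExperiment"))
  modifiedTpm(assay(te), rowData(te)$length, colData(te)$library_size)
}

.gene_mags <- function(tpm, genes) {
  mags <- genes$mag_id[match(rownames(tpm), genes$gene_id)]
  if (anyNA(mags)) {
    orphans <- rownames(tpm)[is.na(mags)]
    warning(length(orphans), " gene(s) with no MAG excluded: ",
            paste(utils::head(orphans), collapse = ", "))
  }
  mags
}

#' Per-MAG expression totals across transcriptome samples
#'
#' Sums modified-TPM over each MAG's genes per sample; optionally divides by
#' the MAG's estimated genome size in Mbp, so large genomes do not dominate
#' purely by gene count. Community share is each MAG's fraction of the
#' per-sample total.
#'
#' @param tpm modified-TPM matrix (genes x samples) or a
#'   `TranscriptExperiment`.
#' @param genes gene table with `gene_id`, `mag_id` (ignored when `tpm` is a
#'   `TranscriptExperiment`, whose `rowData` is used).
#' @param mags MAG table with `mag_id` and `estimated_size` (bp); required
#'   when `normalizeByGenomeSize = TRUE`.
#' @param normalizeByGenomeSize divide totals by genome size in Mbp?
#' @return list with `totals` (MAG x sample matrix), `share` (per-sample
#'   community share, columns summing to 1 where any expression), and
#'   `not_detected` (MAGs with zero expression everywhere).
#' @export
magExpression <- function(tpm, genes = NULL, mags = NULL,
                          normalizeByGenomeSize = FALSE) {
  if (is(tpm, "TranscriptExperiment")) {
    genes <- cbind(gene_id = rownames(tpm),
                   as.data.frame(rowData(tpm)))
    tpm <- transcriptTpm(tpm)
  }
  magv <- .gene_mags(tpm, genes)
  keep <- !is.na(magv)
  totals <- rowsum(tpm[keep, , drop = FALSE], magv[keep])
  if (normalizeByGenomeSize) {
    if (is.null(mags)) stop("mags table needed to normalize by genome size")
    sz <- mags$estimated_size[match(rownames(totals), mags$mag_id)]
    if (anyNA(sz) || any(sz <= 0))
      stop("every MAG needs a positive estimated_size to normalize")
    totals <- totals / (sz / 1e6)
  }
  cs <- colSums(totals)
  share <- sweep(totals, 2, ifelse(cs > 0, cs, 1), `/`)
  list(totals = totals, share = share,
       not_detected = rownames(totals)[rowSums(totals) == 0])
}

.condition_means <- function(totals, condition) {
  # mean per-sample total within each condition (per-sample-then-average)
  vapply(split(seq_along(condition), condition),
         function(j) rowMeans(totals[, j, drop = FALSE]),
         numeric(nrow(totals)))
}

#' Condition share of expression per functional category
#'
#' For each COG category, the percentage of its expression attributable to
#' condition A: `mean per-A-sample category total / (mean-A + mean-B) * 100`.
#' The two percentages sum to 100 by construction.
#'
#' @param tpm modified-TPM matrix or `TranscriptExperiment`.
#' @param genes gene table with `gene_id`, `cog_category` (unused for a
#'   `TranscriptExperiment`).
#' @param condition per-sample labels with exactly two levels (e.g. oxic /
#'   dysoxic); taken from `colData(tpm)$condition` when absent.
#' @return `data.frame`: `cog_category`, `mean_a`, `mean_b`, `percent_a`,
#'   `percent_b`, with condition A the first factor level. Categories with
#'   zero expression everywhere are excluded (attribute
#'   `"excluded_categories"`).
#' @export
categoryConditionProportion <- function(tpm, genes = NULL, condition = NULL) {
  if (is(tpm, "TranscriptExperiment")) {
    if (is.null(condition)) condition <- colData(tpm)$condition
    genes <- cbind(gene_id = rownames(tpm), as.data.frame(rowData(tpm)))
    tpm <- transcriptTpm(tpm)
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2)
    stop("exactly two condition levels required, got ",
         nlevels(condition))
  if (any(table(condition) == 0)) stop("both conditions must have samples")
  cat <- genes$cog_category[match(rownames(tpm), genes$gene_id)]
  keep <- !is.na(cat) & cat != ""
  totals <- rowsum(tpm[keep, , drop = FALSE], cat[keep])
  mm <- .condition_means(totals, condition)
  zero <- rowSums(mm) == 0
  out <- data.frame(cog_category = rownames(totals)[!zero],
                    mean_a = mm[!zero, 1], mean_b = mm[!zero, 2],
                    row.names = NULL)
  out$percent_a <- 100 * out$mean_a / (out$mean_a + out$mean_b)
  out$percent_b <- 100 - out$percent_a
  names(out) <- sub("_a$", paste0("_", levels(condition)[1]), names(out))
  names(out) <- sub("_b$", paste0("_", levels(condition)[2]), names(out))
  attr(out, "excluded_categories") <- rownames(totals)[zero]
  out
}

#' Condition-exclusive and shared expressed features
#'
#' A feature (gene, or MAG after aggregation) is exclusive to a condition
#' when it is detected (value > `threshold`) in at least one of its samples
#' and in none of the other condition's samples.
#'
#' @param tpm modified-TPM matrix or `TranscriptExperiment`.
#' @param condition two-level per-sample labels (from `colData` if omitted).
#' @param level `"gene"` (rows as-is) or `"mag"` (rows aggregated per MAG
#'   first; needs `genes`).
#' @param genes gene table for `level = "mag"` on a plain matrix.
#' @param threshold detection threshold (default 0: any positive value).
#' @return list: `exclusive_a`, `exclusive_b`, `shared` (feature id
#'   vectors), `counts`, and `percent` of all expressed features in each
#'   exclusive set.
#' @export
exclusiveDetection <- function(tpm, condition = NULL,
                               level = c("gene", "mag"), genes = NULL,
                               threshold = 0) {
  level <- match.arg(level)
  if (is(tpm, "TranscriptExperiment")) {
    if (is.null(condition)) condition <- colData(tpm)$condition
    genes <- cbind(gene_id = rownames(tpm), as.data.frame(rowData(tpm)))
    tpm <- transcriptTpm(tpm)
  }
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2, threshold >= 0)
  if (level == "mag") {
    magv <- .gene_mags(tpm, genes)
    keep <- !is.na(magv)
    tpm <- rowsum(tpm[keep, , drop = FALSE], magv[keep])
  }
  a <- condition == levels(condition)[1]
  detA <- rowSums(tpm[, a, drop = FALSE] > threshold) > 0
  detB <- rowSums(tpm[, !a, drop = FALSE] > threshold) > 0
  out <- list(exclusive_a = rownames(tpm)[detA & !detB],
              exclusive_b = rownames(tpm)[detB & !detA],
              shared = rownames(tpm)[detA & detB])
  n_expressed <- sum(detA | detB)
  out$counts <- lengths(out[1:3])
  out$percent <- if (n_expressed > 0)
    100 * out$counts[1:2] / n_expressed else c(0, 0)
  names(out)[1:2] <- paste0("exclusive_", levels(condition))
  out
}

#' Per-MAG expression fold change between conditions
#'
#' Ratio of mean per-sample expression totals, condition A over B (`Inf`
#' when B is silent but A is not; MAGs silent in both are excluded).
#'
#' @param totals per-MAG expression matrix (e.g. `magExpression()$totals`).
#' @param condition two-level per-sample labels; A = first level.
#' @return `data.frame`: `mag_id`, `mean_a`, `mean_b`, `fold_change`.
#' @export
conditionFoldChange <- function(totals, condition) {
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2)
  mm <- .condition_means(totals, condition)
  keep <- rowSums(mm) > 0
  fc <- ifelse(mm[keep, 2] > 0, mm[keep, 1] / mm[keep, 2],
               ifelse(mm[keep, 1] > 0, Inf, NA_real_))
  data.frame(mag_id = rownames(totals)[keep],
             mean_a = mm[keep, 1], mean_b = mm[keep, 2],
             fold_change = fc, row.names = NULL)
}

#' Z-score scaling of a matrix by row, column, or both
#'
#' `(x - mean) / sd` per vector; `"row-then-column"` scales rows first and
#' then columns of the result (heatmap convention). Constant vectors become
#' zeros with a warning.
#'
#' @param m numeric matrix.
#' @param mode `"row"`, `"column"`, or `"row-then-column"`.
#' @return scaled matrix of the same shape.
#' @export
zscoreScale <- function(m, mode = c("row", "column", "row-then-column")) {
  mode <- match.arg(mode)
  scale1 <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning("constant vector scaled to zeros")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  if (mode == "row") t(apply(m, 1, scale1))
  else if (mode == "column") apply(m, 2, scale1)
  else apply(t(apply(m, 1, scale1)), 2, scale1)
}

#' Share of expression with no functional category
#'
#' Per sample (and separately for ultra-small vs other MAGs when a MAG table
#' is given), the percentage of summed modified-TPM from genes lacking a COG
#' category assignment.
#'
#' @param tpm modified-TPM matrix or `TranscriptExperiment`.
#' @param genes gene table with `gene_id`, `mag_id`, `cog_category`.
#' @param mags optional MAG table with `mag_id`, `group`; when given, the
#'   result is split into `ultra_small` and `other` rows.
#' @return matrix of percentages, groups x samples.
#' @export
annotatedFraction <- function(tpm, genes = NULL, mags = NULL) {
  if (is(tpm, "TranscriptExperiment")) {
    genes <- cbind(gene_id = rownames(tpm), as.data.frame(rowData(tpm)))
    tpm <- transcriptTpm(tpm)
  }
  idx <- match(rownames(tpm), genes$gene_id)
  unann <- is.na(genes$cog_category[idx]) | genes$cog_category[idx] == ""
  grp <- if (is.null(mags)) rep("all", nrow(tpm)) else {
    g <- mags$group[match(genes$mag_id[idx], mags$mag_id)]
    ifelse(isUltraSmall(g), "ultra_small", "other")
  }
  tot <- rowsum(tpm, grp)
  un <- rowsum(tpm * unann, grp)
  100 * un / ifelse(tot > 0, tot, 1)
}

#' Top expressed genes across samples
#'
#' Ranks genes by total modified-TPM; optionally restricted to genes with a
#' gene name. Ties are broken by gene id (lexicographic) for determinism.
#' Cold-shock genes (cspA/B/C) are flagged in the output: their apparent
#' expression can be inflated by cold-based sample preservation.
#'
#' @param tpm modified-TPM matrix or `TranscriptExperiment`.
#' @param genes gene table (`gene_id`, `gene_name`).
#' @param k number of genes to return.
#' @param namedOnly restrict to genes with a non-missing `gene_name`?
#' @return `data.frame`: `gene_id`, `gene_name`, `total_tpm`,
#'   `cold_shock_flag`, ordered by decreasing total.
#' @export
topExpressed <- function(tpm, genes = NULL, k = 20, namedOnly = TRUE) {
  stopifnot(k >= 1)
  if (is(tpm, "TranscriptExperiment")) {
    genes <- cbind(gene_id = rownames(tpm), as.data.frame(rowData(tpm)))
    tpm <- transcriptTpm(tpm)
  }
  tot <- rowSums(tpm)
  nm <- genes$gene_name[match(rownames(tpm), genes$gene_id)]
  keep <- if (namedOnly) !is.na(nm) & nm != "" else rep(TRUE, length(tot))
  ids <- rownames(tpm)[keep]
  o <- order(-tot[keep], ids)
  ids <- ids[o][seq_len(min(k, length(ids)))]
  data.frame(gene_id = ids,
             gene_name = nm[match(ids, rownames(tpm))],
             total_tpm = tot[ids],
             cold_shock_flag = grepl("^csp[ABC]$",
                                     nm[match(ids, rownames(tpm))]),
             row.names = NULL)
}
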