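#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' AbundanceExperiment: taxon-by-sample abundance container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `abundance` assay of non-negative values (MAG or OTU rows, sample
#' columns) together with a processing `stage` recorded in `metadata()`:
#' `"counts"` (raw mapped reads), `"normalized"` (counts up-scaled to the
#' deepest sample) or `"relative"` (per-sample proportions). Sample metadata
#' (site, well, fraction, physicochemistry) lives in `colData`.
#'
#' @slot stage character(1), one of `"counts"`, `"normalized"`, `"relative"`.
#'
#' @seealso [normalizeCounts()], [relativeAbundance()], [enrichmentFactors()]
#' @export
setClass("AbundanceExperiment",
  contains = "SummarizedExperiment",
  slots = c(stage = "character")
)

.validAbundanceExperiment <- function(object) {
  msg <- NULL
  m <- assay(object)
  if (!object@stage %in% c("counts", "normalized", "relative"))
    msg <- c(msg, "stage must be one of 'counts', 'normalized', 'relative'")
  if (any(m < 0, na.rm = TRUE))
    msg <- c(msg, "abundance values must be non-negative")
  if (identical(object@stage, "relative") && ncol(m) > 0) {
    cs <- colSums(m)
    bad <- abs(cs - 1) > 1e-9 & cs != 0
    if (any(bad))
      msg <- c(msg, sprintf(
        "relative-abundance columns must sum to 1 (or 0): %s",
        paste(colnames(m)[bad], collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("AbundanceExperiment", .validAbundanceExperiment)

#' Construct an AbundanceExperiment
#'
#' @param abundance numeric matrix, taxa in rows, samples in columns.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata,
#'   rows aligned with the columns of `abundance`.
#' @param stage processing stage of the values; see
#'   [AbundanceExperiment-class].
#' @return An `AbundanceExperiment`.
#' @examples
#' m <- matrix(c(5, 0, 3, 2), 2, 2,
#'             dimnames = list(c("mag1", "mag2"), c("s1", "s2")))
#' ae <- AbundanceExperiment(m)
#' abundanceStage(ae)
#' @export
AbundanceExperiment <- function(abundance, sampleData = NULL,
                                stage = c("counts", "normalized", "relative")) {
  stage <- match.arg(stage)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("taxon", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
  if (is.null(sampleData)) {
    cd <- DataFrame(row.names = colnames(abundance))
  } else {
    cd <- as(sampleData, "DataFrame")
    rownames(cd) <- colnames(abundance)
  }
  se <- SummarizedExperiment(assays = SimpleList(abundance = abundance),
                             colData = cd)
  new("AbundanceExperiment", se, stage = stage)
}

#' TranscriptExperiment: gene-by-sample transcript counts
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#' of mapped transcript reads. `rowData` carries the gene table (`mag_id`,
#' `length` in bp, `cog_category`, `gene_name`, annotation flags); `colData`
#' must contain `library_size` (total reads of the library, at least the
#' mapped column total) and typically a `condition` factor (oxic/dysoxic).
#'
#' @seealso [modifiedTpm()], [magExpression()]
#' @export
setClass("TranscriptExperiment", contains = "SummarizedExperiment")

.validTranscriptExperiment <- function(object) {
  msg <- NULL
  m <- assay(object)
  if (any(m < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  cd <- colData(object)
  if (!"library_size" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'library_size'")
  } else if (ncol(m) > 0 && any(cd$library_size < colSums(m))) {
    msg <- c(msg, "library_size must be >= mapped column totals")
  }
  rd <- rowData(object)
  if (!all(c("mag_id", "length") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'mag_id' and 'length'")
  } else if (nrow(m) > 0 && any(rd$length <= 0)) {
    msg <- c(msg, "gene lengths must be positive")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("TranscriptExperiment", .validTranscriptExperiment)

#' Construct a TranscriptExperiment
#'
#' @param counts integer-like matrix of mapped reads, genes x samples.
#' @param genes `data.frame` with one row per gene: at least `mag_id` and
#'   `length` (bp); optionally `cog_category` (single-letter code or `NA`),
#'   `gene_name`, and logical annotation flags.
#' @param librarySizes numeric vector of per-sample library sizes (reads),
#'   aligned with the columns of `counts`.
#' @param condition optional per-sample condition labels (e.g. `"oxic"`,
#'   `"dysoxic"`).
#' @return A `TranscriptExperiment`.
#' @export
TranscriptExperiment <- function(counts, genes, librarySizes,
                                 condition = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- genes$gene_id
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  cd <- DataFrame(library_size = as.numeric(librarySizes),
                  row.names = colnames(counts))
  if (!is.null(condition)) cd$condition <- condition
  rd <- as(genes, "DataFrame")
  rownames(rd) <- rownames(counts)
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd, rowData = rd)
  new("TranscriptExperiment", se)
}

#' CooccurrenceNetwork: significant-positive-correlation graph over MAGs
#'
#' Undirected graph over MAG abundance profiles in which an edge joins two
#' MAGs whose Spearman rank correlation exceeds `rhoMin` with p-value below
#' `pMax` (positive correlations only). Isolated nodes are retained; MAGs
#' with constant profiles are excluded from pairing and listed in
#' `excluded`.
#'
#' @slot nodes character vector of MAG ids in the network.
#' @slot edges `data.frame` with columns `mag_a`, `mag_b`, `rho`, `p`.
#' @slot thresholds named numeric, `rho_min` and `p_max`.
#' @slot excluded character vector of constant-profile MAGs left out.
#' @seealso [buildNetwork()], [networkComponents()]
#' @export
setClass("CooccurrenceNetwork",
  slots = c(nodes = "character", edges = "data.frame",
            thresholds = "numeric", excluded = "character")
)

setValidity("CooccurrenceNetwork", function(object) {
  msg <- NULL
  e <- object@edges
  need <- c("mag_a", "mag_b", "rho", "p")
  if (!all(need %in% colnames(e)))
    return("edges must have columns mag_a, mag_b, rho, p")
  if (nrow(e)) {
    if (any(e$mag_a == e$mag_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$rho <= 0)) msg <- c(msg, "edges must be positive correlations")
    if (!all(e$mag_a %in% object@nodes) || !all(e$mag_b %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (!all(c("rho_min", "p_max") %in% names(object@thresholds)))
    msg <- c(msg, "thresholds must name rho_min and p_max")
  if (is.null(msg)) TRUE else msg
})

#' CohortSet: partition of MAGs into co-occurrence cohorts
#'
#' Result of Ward-linkage clustering of abundance profiles confirmed by
#' pairwise Spearman correlation. Cohorts are disjoint groups of >= 2 MAGs;
#' MAGs in no confirmed cohort are `unassigned`.
#'
#' @slot assignment `data.frame` with columns `mag_id`, `cohort_id`.
#' @slot stats per-cohort `data.frame`: `cohort_id`, `size`, `median_rho`,
#'   and (after [cohortConsistency()]) preference-uniformity flags.
#' @slot unassigned character vector of singleton/unconfirmed MAG ids.
#' @seealso [detectCohorts()], [cohortConsistency()]
#' @export
setClass("CohortSet",
  slots = c(assignment = "data.frame", stats = "data.frame",
            unassigned = "character")
)

setValidity("CohortSet", function(object) {
  msg <- NULL
  a <- object@assignment
  if (!all(c("mag_id", "cohort_id") %in% colnames(a)))
    return("assignment must have columns mag_id, cohort_id")
  if (anyDuplicated(a$mag_id))
    msg <- c(msg, "cohorts must be disjoint (a MAG in one cohort at most)")
  if (length(intersect(a$mag_id, object@unassigned)))
    msg <- c(msg, "unassigned MAGs cannot also be cohort members")
  if (nrow(a) && any(table(a$cohort_id) < 2))
    msg <- c(msg, "each cohort must have >= 2 members")
  if (is.null(msg)) TRUE else msg
})
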