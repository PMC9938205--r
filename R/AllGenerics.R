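#' @include AllClasses.R
NULL

#' Processing stage of an AbundanceExperiment
#' @param x an `AbundanceExperiment`.
#' @return character(1): `"counts"`, `"normalized"` or `"relative"`.
#' @export
setGeneric("abundanceStage", function(x) standardGeneric("abundanceStage"))

#' @rdname abundanceStage
#' @export
setMethod("abundanceStage", "AbundanceExperiment", function(x) x@stage)

#' Scale every sample up to the deepest sample's read total
#' @param x taxon-by-sample counts: a matrix or an `AbundanceExperiment` at
#'   the `"counts"` stage.
#' @param ... passed to methods.
#' @export
setGeneric("normalizeCounts", function(x, ...) standardGeneric("normalizeCounts"))

#' Per-sample relative abundance
#' @param x taxon-by-sample values: matrix or `AbundanceExperiment`.
#' @param ... passed to methods.
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' Edges of a co-occurrence network
#' @param x a `CooccurrenceNetwork`.
#' @return `data.frame` with columns `mag_a`, `mag_b`, `rho`, `p`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' Nodes of a co-occurrence network
#' @param x a `CooccurrenceNetwork`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' Cohort membership table
#' @param x a `CohortSet`.
#' @return `data.frame` with columns `mag_id`, `cohort_id`.
#' @export
setGeneric("cohortAssignment", function(x) standardGeneric("cohortAssignment"))

#' @rdname cohortAssignment
#' @export
setMethod("cohortAssignment", "CohortSet", function(x) x@assignment)

#' Per-cohort statistics
#' @param x a `CohortSet`.
#' @export
setGeneric("cohortStats", function(x) standardGeneric("cohortStats"))

#' @rdname cohortStats
#' @export
setMethod("cohortStats", "CohortSet", function(x) x@stats)

#' MAGs assigned to no cohort
#' @param x a `CohortSet`.
#' @export
setGeneric("unassignedMags", function(x) standardGeneric("unassignedMags"))

#' @rdname unassignedMags
#' @export
setMethod("unassignedMags", "CohortSet", function(x) x@unassigned)

setMethod("show", "AbundanceExperiment", function(object) {
  cat(sprintf("AbundanceExperiment: %d taxa x %d samples (stage: %s)\n",
              nrow(object), ncol(object), object@stage))
  callNextMethod()
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf(
    "CooccurrenceNetwork: %d nodes, %d edges (rho > %g, p < %g)\n",
    length(object@nodes), nrow(object@edges),
    object@thresholds[["rho_min"]], object@thresholds[["p_max"]]))
  deg <- table(factor(c(object@edges$mag_a, object@edges$mag_b),
                      levels = object@nodes))
  cat(sprintf("  isolated nodes: %d; excluded (constant profile): %d\n",
              sum(deg == 0), length(object@excluded)))
})

setMethod("show", "CohortSet", function(object) {
  sizes <- if (nrow(object@stats)) object@stats$size else integer(0)
  cat(sprintf(
    "CohortSet: %d cohorts (%d MAGs assigned, %d unassigned)\n",
    nrow(object@stats), nrow(object@assignment),
    length(object@unassigned)))
  if (length(sizes))
    cat(sprintf("  cohort sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
})
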