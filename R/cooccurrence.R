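#' @include AllClasses.R AllGenerics.R correlation.R
NULL

#' Build the significant-positive-correlation co-occurrence network
#'
#' An edge joins two MAGs whose abundance profiles have Spearman rho >
#' `rhoMin` with p < `pMax` (t-approximation, two-sided). Only positive
#' correlations form edges; isolated nodes are retained. MAGs with a
#' constant profile have no defined rank correlation and are excluded from
#' pairing (kept in `excluded`).
#'
#' @param rel relative-abundance matrix (MAGs x samples, >= 3 samples) or
#'   `AbundanceExperiment`.
#' @param rhoMin correlation threshold (default 0.8, strict).
#' @param pMax p-value threshold (default 0.001, strict).
#' @return a [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(rel, rhoMin = 0.8, pMax = 0.001) {
  m <- .as_abundance_matrix(rel)
  if (ncol(m) < 3) stop("need >= 3 samples to build a network")
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  excluded <- rownames(m)[const]
  if (length(excluded))
    message(length(excluded), " constant-profile MAG(s) excluded from pairing")
  mm <- m[!const, , drop = FALSE]
  edges <- data.frame(mag_a = character(), mag_b = character(),
                      rho = numeric(), p = numeric())
  if (nrow(mm) >= 2) {
    rho <- stats::cor(t(mm), method = "spearman")
    p <- .rho_t_p(rho, ncol(mm))
    iu <- which(upper.tri(rho) & rho > rhoMin & p < pMax, arr.ind = TRUE)
    if (nrow(iu))
      edges <- data.frame(mag_a = rownames(mm)[iu[, 1]],
                          mag_b = rownames(mm)[iu[, 2]],
                          rho = rho[iu], p = p[iu])
  }
  new("CooccurrenceNetwork", nodes = rownames(mm), edges = edges,
      thresholds = c(rho_min = rhoMin, p_max = pMax), excluded = excluded)
}

#' Convert a CooccurrenceNetwork to an igraph graph
#' @param net a [CooccurrenceNetwork-class].
#' @return an undirected `igraph` graph with `rho` and `p` edge attributes.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

#' Connected components of the co-occurrence network
#'
#' @param net a [CooccurrenceNetwork-class].
#' @return list with `members` (list of node-id vectors, sorted by
#'   decreasing size) and `isolated` (nodes with no edge).
#' @export
networkComponents <- function(net) {
  g <- asIgraph(net)
  comp <- igraph::components(g)
  grp <- split(names(comp$membership), comp$membership)
  grp <- grp[order(-lengths(grp), vapply(grp, min, ""))]
  isolated <- names(grp)[lengths(grp) == 1]
  list(members = unname(grp[lengths(grp) > 1]),
       isolated = unlist(grp[lengths(grp) == 1], use.names = FALSE))
}

.median_pairwise_rho <- function(m) {
  if (nrow(m) < 2) return(NA_real_)
  rho <- stats::cor(t(m), method = "spearman")
  stats::median(rho[upper.tri(rho)])
}

# cluster-level confirmation: the median pairwise rho must reach the
# threshold, and so must every member's median rho to the other members —
# the per-member condition catches small foreign subgroups absorbed into a
# large cluster, which the (robust) cluster median alone cannot see.
.confirm_cluster <- function(m, confirmRho) {
  if (nrow(m) < 2) return(list(ok = FALSE, median = NA_real_))
  rho <- stats::cor(t(m), method = "spearman")
  med <- stats::median(rho[upper.tri(rho)])
  if (is.na(med) || med < confirmRho)
    return(list(ok = FALSE, median = med))
  diag(rho) <- NA
  member_med <- apply(rho, 1, stats::median, na.rm = TRUE)
  list(ok = all(!is.na(member_med)) && min(member_med) >= confirmRho,
       median = med)
}

#' Detect co-occurrence cohorts by confirmed Ward clustering
#'
#' Per-MAG abundance profiles are standardized (z-score across samples, so
#' shape rather than magnitude drives grouping), clustered by Ward's
#' minimum-variance linkage (ward.D2) on Euclidean distances, and the
#' dendrogram is cut by a confirmation rule: a cluster is accepted as a
#' cohort when the median pairwise Spearman rho among its members is at
#' least `confirmRho`; failing clusters are split at their top merge and the
#' parts re-examined recursively. Singletons end up unassigned. Merge-order
#' ties are resolved by lexicographic MAG id, making the procedure fully
#' deterministic.
#'
#' @param rel relative-abundance matrix (MAGs x samples, >= 3 samples) or
#'   `AbundanceExperiment`.
#' @param confirmRho confirmation threshold on the median pairwise Spearman
#'   rho (default 0.8, matching the network edge threshold).
#' @param standardize z-score profiles per MAG before clustering (default
#'   `TRUE`)?
#' @return a [CohortSet-class].
#' @export
detectCohorts <- function(rel, confirmRho = 0.8, standardize = TRUE) {
  m <- .as_abundance_matrix(rel)
  if (ncol(m) < 3) stop("need >= 3 samples to detect cohorts")
  m <- m[order(rownames(m)), , drop = FALSE]   # deterministic tie order
  if (nrow(m) < 2)
    return(new("CohortSet",
               assignment = data.frame(mag_id = character(),
                                       cohort_id = character()),
               stats = data.frame(cohort_id = character(), size = integer(),
                                  median_rho = numeric()),
               unassigned = rownames(m)))
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  prof <- if (standardize) {
    # standardized rank profiles: Euclidean distance between z-scored rank
    # vectors is a monotone function of Spearman rho, so the Ward tree's
    # geometry agrees with the rank-correlation confirmation statistic
    mz <- t(apply(m, 1, rank))
    mz[!const, ] <- t(apply(mz[!const, , drop = FALSE], 1,
                            function(r) (r - mean(r)) / stats::sd(r)))
    mz[const, ] <- 0
    mz
  } else m
  hc <- stats::hclust(stats::dist(prof), method = "ward.D2")
  # recursive confirmation over the merge tree
  members_of <- function(node) {
    if (node < 0) return(rownames(m)[-node])
    c(members_of(hc$merge[node, 1]), members_of(hc$merge[node, 2]))
  }
  cohorts <- list()
  walk <- function(node) {
    ids <- members_of(node)
    if (length(ids) >= 2) {
      conf <- .confirm_cluster(m[ids, , drop = FALSE], confirmRho)
      if (conf$ok) {
        cohorts[[length(cohorts) + 1L]] <<- list(ids = sort(ids),
                                                 rho = conf$median)
        return(invisible())
      }
    }
    if (node < 0) return(invisible())  # unconfirmed singleton path
    walk(hc$merge[node, 1])
    walk(hc$merge[node, 2])
  }
  walk(nrow(hc$merge))
  # deterministic cohort ids: order by first member id
  if (length(cohorts)) {
    ord <- order(vapply(cohorts, function(co) co$ids[1], ""))
    cohorts <- cohorts[ord]
  }
  assignment <- do.call(rbind, lapply(seq_along(cohorts), function(i)
    data.frame(mag_id = cohorts[[i]]$ids,
               cohort_id = sprintf("cohort%03d", i))))
  if (is.null(assignment))
    assignment <- data.frame(mag_id = character(), cohort_id = character())
  stats_df <- do.call(rbind, lapply(seq_along(cohorts), function(i)
    data.frame(cohort_id = sprintf("cohort%03d", i),
               size = length(cohorts[[i]]$ids),
               median_rho = cohorts[[i]]$rho)))
  if (is.null(stats_df))
    stats_df <- data.frame(cohort_id = character(), size = integer(),
                           median_rho = numeric())
  new("CohortSet", assignment = assignment, stats = stats_df,
      unassigned = setdiff(rownames(m), assignment$mag_id))
}

#' Preference consistency of cohorts
#'
#' A cohort is uniform for a grouping (fraction preference or DO/oxygen
#' preference) when every member carries the same enrichment class, with
#' exclusive classes counted as enriched on their side. Members missing a
#' class make the cohort indeterminate (`NA`) for that grouping.
#'
#' @param cohorts a [CohortSet-class].
#' @param fractionEnrichment,doEnrichment `data.frame`s from
#'   [enrichmentFactors()] (columns `taxon_id`, `class`) for the
#'   planktonic-vs-attached and oxic-vs-dysoxic contrasts.
#' @return list with `per_cohort` (`data.frame`: `cohort_id`,
#'   `fraction_uniform`, `do_uniform`) and `counts` (named: cohorts uniform
#'   for each grouping, over the number of determinate cohorts).
#' @export
cohortConsistency <- function(cohorts, fractionEnrichment, doEnrichment) {
  stopifnot(is(cohorts, "CohortSet"))
  simplify_class <- function(cl) {
    cl <- sub("^exclusive-", "enriched-", cl)
    cl
  }
  uniform <- function(members, enr) {
    cl <- enr$class[match(members, enr$taxon_id)]
    if (anyNA(cl)) return(NA)
    length(unique(simplify_class(cl))) == 1
  }
  a <- cohortAssignment(cohorts)
  per <- do.call(rbind, lapply(split(a$mag_id, a$cohort_id), function(ids)
    data.frame(fraction_uniform = uniform(ids, fractionEnrichment),
               do_uniform = uniform(ids, doEnrichment))))
  per <- data.frame(cohort_id = rownames(per), per, row.names = NULL)
  list(per_cohort = per,
       counts = c(fraction_uniform = sum(per$fraction_uniform, na.rm = TRUE),
                  do_uniform = sum(per$do_uniform, na.rm = TRUE),
                  n_cohorts = nrow(per)))
}
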