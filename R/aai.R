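#' @include AllClasses.R
NULL

# Family-level AAI band (percent identity) used for novelty calls.
.AAI_FAMILY_BAND <- c(45, 65)

.check_hits <- function(hits) {
  need <- c("query_id", "subject_id", "query_genome", "subject_genome",
            "percent_identity", "alignment_length", "query_length",
            "subject_length", "bitscore")
  miss <- setdiff(need, colnames(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(hits$percent_identity) |
                 hits$percent_identity < 0 | hits$percent_identity > 100 |
                 hits$alignment_length <= 0 |
                 hits$query_length <= 0 | hits$subject_length <= 0)
  if (length(bad))
    stop("malformed hit row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  hits
}

#' Filter protein alignment hits for AAI
#'
#' Keeps matches with at least `minIdentity` percent identity over at least
#' `minCoverage` of the alignable length. The coverage denominator is the
#' shorter of the two proteins (the usual AAI convention); `literal` mode
#' instead applies no length denominator, reading the threshold against the
#' alignment length alone (i.e. only the identity filter acts).
#'
#' @param hits `data.frame` of blastp-style hits: `query_id`, `subject_id`,
#'   `query_genome`, `subject_genome`, `percent_identity`,
#'   `alignment_length`, `query_length`, `subject_length`, `bitscore`.
#' @param minIdentity percent identity floor, inclusive (default 30).
#' @param minCoverage alignment-coverage floor, inclusive (default 0.70).
#' @param literal disable the shorter-protein coverage denominator.
#' @return the retained subset of `hits`.
#' @export
filterHits <- function(hits, minIdentity = 30, minCoverage = 0.70,
                       literal = FALSE) {
  hits <- .check_hits(hits)
  keep <- hits$percent_identity >= minIdentity
  if (!literal) {
    shorter <- pmin(hits$query_length, hits$subject_length)
    keep <- keep & hits$alignment_length >= minCoverage * shorter
  }
  hits[keep, , drop = FALSE]
}

#' Best hits per query protein, one-way or reciprocal
#'
#' One-way: for each query protein the subject with the highest bitscore
#' (ties broken by higher identity, then lexicographic subject id).
#' Reciprocal: protein pairs that are mutual best hits in the two
#' directions of a genome pair.
#'
#' @param hits filtered hit table for one ordered or unordered genome pair
#'   (both directions present for reciprocal mode).
#' @param mode `"reciprocal"` (default) or `"one-way"`.
#' @return subset of `hits`: one row per retained pair. In reciprocal mode
#'   rows from the first direction (lexicographically smaller query genome)
#'   represent each mutual pair.
#' @export
bestHits <- function(hits, mode = c("reciprocal", "one-way")) {
  mode <- match.arg(mode)
  if (!nrow(hits)) return(hits)
  best_oneway <- function(h) {
    if (!nrow(h)) return(h)
    o <- order(h$query_id, -h$bitscore, -h$percent_identity, h$subject_id)
    h <- h[o, , drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  dirs <- split(hits, paste(hits$query_genome, hits$subject_genome, sep = "\r"))
  if (mode == "one-way")
    return(do.call(rbind, c(lapply(dirs, best_oneway),
                            list(make.row.names = FALSE))))
  gpair <- vapply(strsplit(names(dirs), "\r", fixed = TRUE),
                  function(g) paste(sort(g), collapse = "\r"), "")
  out <- lapply(unique(gpair), function(gp) {
    two <- dirs[gpair == gp]
    if (length(two) == 1) {       # only one direction present: no mutuals
      h <- two[[1]][0, , drop = FALSE]
      return(h)
    }
    g <- sort(strsplit(gp, "\r", fixed = TRUE)[[1]])
    fwd <- best_oneway(two[[which(vapply(two, function(h)
      h$query_genome[1] == g[1], TRUE))]])
    rev <- best_oneway(two[[which(vapply(two, function(h)
      h$query_genome[1] == g[2], TRUE))]])
    mutual <- paste(fwd$query_id, fwd$subject_id) %in%
      paste(rev$subject_id, rev$query_id)
    fwd[mutual, , drop = FALSE]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.family_call <- function(aai) {
  if (is.na(aai)) NA_character_
  else if (aai < .AAI_FAMILY_BAND[1]) "below-band"
  else if (aai > .AAI_FAMILY_BAND[2]) "above-band"
  else "within-family-band"
}

#' Average amino-acid identity between two genomes
#'
#' Unweighted mean percent identity over filtered best-hit protein pairs.
#' An AAI in the 45-65% family band indicates the two genomes likely belong
#' to the same family; below the band the query is novel at family level or
#' higher.
#'
#' @param hits raw hit table containing (at least) the two genomes'
#'   comparisons.
#' @param genomeA,genomeB genome ids.
#' @param mode `"reciprocal"` (symmetric, default) or `"one-way"` (A as
#'   query).
#' @param minIdentity,minCoverage,literal passed to [filterHits()].
#' @return `data.frame` row: `genome_a`, `genome_b`, `aai`, `n_pairs`,
#'   `mode`, `family_call`. `aai` is `NA` with `n_pairs = 0` when no pair
#'   survives filtering.
#' @export
aai <- function(hits, genomeA, genomeB, mode = c("reciprocal", "one-way"),
                minIdentity = 30, minCoverage = 0.70, literal = FALSE) {
  mode <- match.arg(mode)
  sel <- (hits$query_genome == genomeA & hits$subject_genome == genomeB) |
    (hits$query_genome == genomeB & hits$subject_genome == genomeA)
  h <- filterHits(hits[sel, , drop = FALSE], minIdentity, minCoverage,
                  literal)
  if (mode == "one-way")
    h <- h[h$query_genome == genomeA, , drop = FALSE]
  pairs <- bestHits(h, mode)
  val <- if (nrow(pairs)) mean(pairs$percent_identity) else NA_real_
  data.frame(genome_a = genomeA, genome_b = genomeB, aai = val,
             n_pairs = nrow(pairs), mode = mode,
             family_call = .family_call(val), row.names = NULL)
}

#' Maximum-AAI novelty summary per query genome
#'
#' For each query genome, the maximum AAI over a set of reference genomes
#' and the family-band call at that maximum. Queries with no retained hit
#' pair against any reference are reported `no-confident-match`.
#'
#' @param hits raw hit table covering query-vs-reference comparisons.
#' @param queries character vector of query genome ids.
#' @param references character vector of reference genome ids.
#' @param ... passed to [aai()] (mode, filters).
#' @return `data.frame`: `genome`, `max_aai`, `best_reference`,
#'   `family_call` (or `"no-confident-match"`), `n_pairs` at the maximum.
#' @export
noveltySummary <- function(hits, queries, references, ...) {
  rows <- lapply(queries, function(q) {
    res <- do.call(rbind, lapply(references, function(r)
      aai(hits, q, r, ...)))
    res <- res[!is.na(res$aai), , drop = FALSE]
    if (!nrow(res))
      return(data.frame(genome = q, max_aai = NA_real_,
                        best_reference = NA_character_,
                        family_call = "no-confident-match", n_pairs = 0L))
    best <- res[which.max(res$aai), ]
    data.frame(genome = q, max_aai = best$aai,
               best_reference = best$genome_b,
               family_call = best$family_call, n_pairs = best$n_pairs)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise AAI matrix over a genome set
#' @param hits raw hit table.
#' @param genomes genome ids to compare.
#' @param ... passed to [aai()].
#' @return symmetric numeric matrix of AAI values (`NA` where undefined),
#'   100 on the diagonal.
#' @export
aaiMatrix <- function(hits, genomes, ...) {
  n <- length(genomes)
  m <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  diag(m) <- 100
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    m[i, j] <- m[j, i] <- aai(hits, genomes[i], genomes[j], ...)$aai
  }
  m
}
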