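suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# small named taxon x sample matrix
toy_matrix <- function(values, taxa = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- taxa %||% paste0("t", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one blastp-style hit row
hit_row <- function(query_id, subject_id, qg, sg, pid, alen,
                    qlen = 300, slen = 300, bits = pid * 3) {
  data.frame(query_id = query_id, subject_id = subject_id,
             query_genome = qg, subject_genome = sg,
             percent_identity = pid, alignment_length = alen,
             query_length = qlen, subject_length = slen, bitscore = bits)
}

# reciprocal one-to-one hit table between two genomes at given identities
reciprocal_hits <- function(ga, gb, idents, qlen = 300) {
  n <- length(idents)
  alen <- round(0.8 * qlen)
  fwd <- hit_row(sprintf("%s_p%d", ga, 1:n), sprintf("%s_p%d", gb, 1:n),
                 ga, gb, idents, alen, qlen, qlen)
  rev <- hit_row(sprintf("%s_p%d", gb, 1:n), sprintf("%s_p%d", ga, 1:n),
                 gb, ga, idents, alen, qlen, qlen)
  rbind(fwd, rev)
}

# brute-force AAI oracle: filter, per-query best (bitscore, identity, id),
# mutual pairs, unweighted mean -- written as plain loops, independent of
# the package's vectorized path
aai_bruteforce <- function(hits, ga, gb, min_id = 30, min_cov = 0.7) {
  keep <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    shorter <- min(h$query_length, h$subject_length)
    if (h$percent_identity >= min_id && h$alignment_length >= min_cov * shorter)
      keep[[length(keep) + 1]] <- h
  }
  if (!length(keep)) return(NA_real_)
  hh <- do.call(rbind, keep)
  best_of <- function(qg, sg) {
    d <- hh[hh$query_genome == qg & hh$subject_genome == sg, , drop = FALSE]
    out <- list()
    for (q in unique(d$query_id)) {
      dq <- d[d$query_id == q, , drop = FALSE]
      dq <- dq[order(-dq$bitscore, -dq$percent_identity, dq$subject_id), ,
               drop = FALSE]
      out[[q]] <- dq[1, ]
    }
    do.call(rbind, out)
  }
  fwd <- best_of(ga, gb); rev <- best_of(gb, ga)
  if (is.null(fwd) || is.null(rev)) return(NA_real_)
  vals <- c()
  for (i in seq_len(nrow(fwd))) {
    j <- which(rev$query_id == fwd$subject_id[i])
    if (length(j) && rev$subject_id[j] == fwd$query_id[i])
      vals <- c(vals, fwd$percent_identity[i])
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# independent Spearman oracle: explicit average-rank transform then the
# textbook product-moment formula
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# standard cluster purity against true labels
cluster_purity <- function(truth, found) {
  sum(vapply(split(truth, found), function(x) max(table(x)), 1)) /
    length(truth)
}
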