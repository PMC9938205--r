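#' @include AllClasses.R
NULL

.rho_t_p <- function(rho, n) {
  # two-sided p via the t approximation with n-2 df
  ifelse(abs(rho) >= 1, 0,
         2 * stats::pt(-abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2))
}

#' Spearman rank correlation with significance
#'
#' Ties receive average ranks; rho is the product-moment correlation of the
#' ranks. The default two-sided p-value uses the t approximation with n - 2
#' degrees of freedom; a seeded Monte-Carlo permutation p is available for
#' validation.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @param pMethod `"t-approx"` (default) or `"permutation"`.
#' @param nPerm permutations for `pMethod = "permutation"`.
#' @param seed integer seed for the permutation draw.
#' @return `data.frame` row: `coefficient`, `p_value`, `n`, `method`.
#' @examples
#' spearmanTest(1:5, c(2, 4, 6, 8, 10))$coefficient  # 1
#' @export
spearmanTest <- function(x, y, pMethod = c("t-approx", "permutation"),
                         nPerm = 10000, seed = NULL) {
  pMethod <- match.arg(pMethod)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(coefficient = NA_real_, p_value = NA_real_,
                      n = length(x), method = "spearman"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (pMethod == "t-approx") {
    p <- .rho_t_p(rho, n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- vapply(seq_len(nPerm), function(i)
      abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12, TRUE)
    p <- (1 + sum(ge)) / (nPerm + 1)
  }
  data.frame(coefficient = rho, p_value = p, n = n, method = "spearman")
}

#' Pearson product-moment correlation with significance
#'
#' Two-sided t-test with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `data.frame` row: `coefficient`, `p_value`, `n`, `method`.
#' @export
pearsonTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
    return(data.frame(coefficient = NA_real_, p_value = NA_real_,
                      n = length(x), method = "pearson"))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(coefficient = unname(ct$estimate), p_value = ct$p.value,
             n = length(x), method = "pearson")
}

#' Correlation screen of feature profiles against environmental parameters
#'
#' Computes every (feature row, parameter) correlation, flags entries at the
#' raw significance threshold (no multiplicity correction by default,
#' mirroring screened-heatmap practice; optional Benjamini-Hochberg), and
#' summarizes per-parameter significant positive/negative counts. Missing
#' chemistry values are handled pairwise-complete with the per-entry n
#' recorded.
#'
#' @param m feature x sample matrix (MAG relative abundance, per-MAG
#'   modified-TPM, ...) or `AbundanceExperiment`.
#' @param env sample x parameter `data.frame` of environmental values,
#'   rows aligned with the columns of `m`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha significance threshold on the (possibly adjusted) p-value.
#' @param adjust apply Benjamini-Hochberg across all entries?
#' @return list with `entries` (`data.frame`: `x_id`, `y_id`, `method`,
#'   `coefficient`, `p_value`, `n`, `significant`), `summary`
#'   (per-parameter counts of significant positive/negative entries) and
#'   `masked` (wide feature x parameter matrix with non-significant cells
#'   `NA`).
#' @export
correlationScreen <- function(m, env, method = c("spearman", "pearson"),
                              alpha = 0.05, adjust = FALSE) {
  method <- match.arg(method)
  m <- .as_abundance_matrix(m)
  env <- as.data.frame(env)
  stopifnot(ncol(m) == nrow(env))
  test1 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_, sum(ok)))
    r <- if (method == "spearman") spearmanTest(x[ok], y[ok])
         else pearsonTest(x[ok], y[ok])
    c(r$coefficient, r$p_value, r$n)
  }
  grid <- expand.grid(x_id = rownames(m), y_id = colnames(env),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(xi, yi) test1(m[xi, ], env[[yi]]),
                grid$x_id, grid$y_id)
  entries <- data.frame(grid, method = method,
                        coefficient = res[1, ], p_value = res[2, ],
                        n = as.integer(res[3, ]), row.names = NULL)
  p_use <- if (adjust) stats::p.adjust(entries$p_value, "BH")
           else entries$p_value
  entries$significant <- !is.na(p_use) & p_use < alpha
  sig <- entries[entries$significant, , drop = FALSE]
  summary <- do.call(rbind, lapply(colnames(env), function(yv) {
    s <- sig[sig$y_id == yv, , drop = FALSE]
    data.frame(parameter = yv,
               n_positive = sum(s$coefficient > 0),
               n_negative = sum(s$coefficient < 0))
  }))
  masked <- matrix(NA_real_, nrow(m), ncol(env),
                   dimnames = list(rownames(m), colnames(env)))
  if (nrow(sig))
    masked[cbind(sig$x_id, sig$y_id)] <- sig$coefficient
  list(entries = entries, summary = summary, masked = masked)
}
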