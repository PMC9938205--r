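#' @include AllClasses.R
NULL

# Lineage-specific single-copy marker set sizes used for ultra-small
# prokaryote bins: 51 bacterial markers (Dependentiae), 43 (Patescibacteria),
# 38 archaeal markers (DPANN lineages).
.SCG_SET_SIZES <- c(bact51 = 51L, bact43 = 43L, arch38 = 38L)

#' Marker set size for an SCG set label
#' @param scgSet one of `"bact51"`, `"bact43"`, `"arch38"`.
#' @return integer marker count.
#' @export
scgSetSize <- function(scgSet) {
  if (!all(scgSet %in% names(.SCG_SET_SIZES)))
    stop("unknown SCG set label: ",
         paste(setdiff(scgSet, names(.SCG_SET_SIZES)), collapse = ", "))
  unname(.SCG_SET_SIZES[scgSet])
}

#' SCG set used by a lineage group
#' @param group lineage group label(s): `"Patescibacteria"`,
#'   `"Dependentiae"`, or a DPANN lineage (prefix `"DPANN"`).
#' @return character vector of SCG set labels.
#' @export
scgSetForGroup <- function(group) {
  out <- rep("bact43", length(group))
  out[group == "Dependentiae"] <- "bact51"
  out[startsWith(group, "DPANN")] <- "arch38"
  out[!(group %in% "Dependentiae") & !startsWith(group, "DPANN") &
        !(group %in% "Patescibacteria")] <- NA_character_
  out
}

#' Completeness and contamination from single-copy gene copy numbers
#'
#' Completeness is the fraction of the lineage's marker set observed at least
#' once; contamination is the fraction observed in two or more copies
#' (duplicated markers), paralleling the CheckM convention.
#'
#' @param copies named integer vector of marker copy numbers (absent markers
#'   may be omitted or present with count 0).
#' @param scgSet marker set label (`"bact51"`, `"bact43"`, `"arch38"`),
#'   fixing the denominator at 51/43/38.
#' @return named numeric: `completeness`, `contamination` (fractions).
#' @examples
#' scgCompleteness(stats::setNames(rep(1L, 43), paste0("m", 1:43)), "bact43")
#' @export
scgCompleteness <- function(copies, scgSet) {
  size <- scgSetSize(scgSet)
  copies <- copies[copies > 0]
  if (length(copies) > size)
    stop("more distinct markers (", length(copies),
         ") than the declared set size (", size, ")")
  if (any(copies != round(copies)) || any(copies < 0))
    stop("marker copy numbers must be non-negative integers")
  c(completeness = sum(copies >= 1) / size,
    contamination = sum(copies >= 2) / size)
}

#' Estimated genome size from bin size, completeness and contamination
#'
#' `(bin size - bin size * contamination) / completeness`: the contaminated
#' fraction is removed and the clean residue is scaled up by the estimated
#' completeness.
#'
#' @param binSize assembled bin size in bp.
#' @param completeness fraction in (0, 1].
#' @param contamination fraction >= 0.
#' @return estimated genome size in bp (vectorized).
#' @examples
#' estimateGenomeSize(800000, 0.8, 0.05)  # 950000
#' @export
estimateGenomeSize <- function(binSize, completeness, contamination = 0) {
  if (any(binSize <= 0)) stop("binSize must be positive")
  if (any(completeness <= 0))
    stop("estimated genome size is undefined at completeness 0")
  if (any(completeness > 1) || any(contamination < 0))
    stop("completeness must be in (0,1] and contamination >= 0")
  (binSize - binSize * contamination) / completeness
}

#' Quality-tier filtering of MAGs
#'
#' Tier semantics follow the reporting conventions for groundwater MAG sets:
#' the 50% and 70% tiers use a strict lower bound on completeness
#' (`completeness > min`), the 80% and 90% tiers are inclusive
#' (`completeness >= min`); contamination is always strict (`< max`).
#'
#' @param mags `data.frame` with columns `mag_id`, `completeness`,
#'   `contamination` (fractions).
#' @param minCompleteness completeness threshold in \[0, 1\].
#' @param maxContamination contamination ceiling (default 0.05).
#' @param inclusive if `TRUE` the completeness bound is `>=`; if `NULL`
#'   (default) it is inferred from the threshold: inclusive for >= 0.8,
#'   strict below.
#' @return the filtered subset of `mags`, with a `tier` column tagging the
#'   highest tier (`"50"`, `"70"`, `"80"`, `"90"`) each MAG reaches.
#' @export
qualityFilter <- function(mags, minCompleteness = 0.5,
                          maxContamination = 0.05, inclusive = NULL) {
  stopifnot(minCompleteness >= 0, minCompleteness <= 1,
            maxContamination >= 0, maxContamination <= 1)
  if (is.null(inclusive)) inclusive <- minCompleteness >= 0.8
  ok_c <- if (inclusive) mags$completeness >= minCompleteness
          else mags$completeness > minCompleteness
  keep <- mags[ok_c & mags$contamination < maxContamination, , drop = FALSE]
  keep$tier <- qualityTier(keep$completeness)
  keep
}

#' Highest quality tier reached by a completeness value
#' @param completeness numeric vector of fractions.
#' @return character: `"90"`, `"80"`, `"70"`, `"50"`, or `NA` below all
#'   tiers. 50/70 are strict bounds, 80/90 inclusive.
#' @export
qualityTier <- function(completeness) {
  out <- rep(NA_character_, length(completeness))
  out[completeness > 0.5] <- "50"
  out[completeness > 0.7] <- "70"
  out[completeness >= 0.8] <- "80"
  out[completeness >= 0.9] <- "90"
  out
}

#' Gene density per Mbp of estimated genome
#' @param geneCount number of genes (copy number) in the genome.
#' @param estimatedSize estimated genome size in bp.
#' @return genes per Mbp (vectorized).
#' @examples
#' genesPerMbp(3, 1.5e6)  # 2
#' @export
genesPerMbp <- function(geneCount, estimatedSize) {
  if (any(estimatedSize <= 0)) stop("estimatedSize must be positive")
  if (any(geneCount < 0)) stop("geneCount must be non-negative")
  geneCount * 1e6 / estimatedSize
}

#' Redox class of a groundwater sample from dissolved oxygen
#'
#' Oxic groundwater is DO > 3 g/m3; lower classes use configurable
#' half-open intervals \[low, high): defaults anoxic DO < 0.1, suboxic
#' \[0.1, 0.3), dysoxic \[0.3, 3\].
#'
#' @param do dissolved oxygen in g/m3 (numeric vector).
#' @param thresholds named numeric: `anoxic_max` (default 0.1),
#'   `suboxic_max` (default 0.3), `oxic_min` (fixed default 3).
#' @return factor with levels anoxic, suboxic, dysoxic, oxic.
#' @examples
#' classifyRedox(c(0.05, 0.2, 0.37, 3, 7.5))
#' @export
classifyRedox <- function(do, thresholds = c(anoxic_max = 0.1,
                                             suboxic_max = 0.3,
                                             oxic_min = 3)) {
  if (any(do < 0)) stop("dissolved oxygen cannot be negative")
  stopifnot(thresholds[["anoxic_max"]] <= thresholds[["suboxic_max"]],
            thresholds[["suboxic_max"]] <= thresholds[["oxic_min"]])
  out <- rep("dysoxic", length(do))
  out[do < thresholds[["suboxic_max"]]] <- "suboxic"
  out[do < thresholds[["anoxic_max"]]] <- "anoxic"
  out[do > thresholds[["oxic_min"]]] <- "oxic"
  factor(out, levels = c("anoxic", "suboxic", "dysoxic", "oxic"))
}

#' Genome metrics table for a MAG set
#'
#' Derives completeness/contamination from a long-format SCG table when
#' given, computes estimated genome size, and tags quality tiers.
#'
#' @param mags `data.frame`: `mag_id`, `group`, `bin_size`, and (unless
#'   `scg` is supplied) `completeness` and `contamination`.
#' @param scg optional long-format SCG table: `mag_id`, `marker_id`,
#'   `copies`, `scg_set`; when present it overrides the completeness and
#'   contamination columns.
#' @return `mags` with columns `completeness`, `contamination`,
#'   `estimated_size` (NA where completeness is 0) and `tier`.
#' @export
genomeMetrics <- function(mags, scg = NULL) {
  mags <- as.data.frame(mags)
  if (!is.null(scg)) {
    split_scg <- split(scg, scg$mag_id)
    cc <- t(vapply(mags$mag_id, function(id) {
      s <- split_scg[[id]]
      if (is.null(s)) return(c(completeness = 0, contamination = 0))
      scgCompleteness(stats::setNames(s$copies, s$marker_id), s$scg_set[1])
    }, numeric(2)))
    mags$completeness <- cc[, "completeness"]
    mags$contamination <- cc[, "contamination"]
  }
  mags$estimated_size <- ifelse(
    mags$completeness > 0,
    (mags$bin_size - mags$bin_size * mags$contamination) / mags$completeness,
    NA_real_)
  mags$tier <- qualityTier(mags$completeness)
  mags
}

#' Is a lineage group ultra-small?
#' @param group character vector of lineage groups.
#' @return logical: Patescibacteria, Dependentiae and DPANN lineages.
#' @export
isUltraSmall <- function(group) {
  group %in% c("Patescibacteria", "Dependentiae") | startsWith(group, "DPANN")
}
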