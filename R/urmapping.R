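## Flag-filtered unmapped-read counting, per-individual mapping fractions,
## allele-frequency depletion curves and cross-population statistics.

FLAG_UNMAPPED <- 4L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' Count reads under the standard flag filters
#'
#' Totals exclude secondary (0x100) and supplementary (0x800) records, so
#' each read is counted once; mapped reads additionally exclude records with
#' the unmapped bit (0x4). Counting is stream-order invariant and mergeable.
#'
#' @param flags Integer vector of SAM flags, or a data.frame with a
#'   \code{flag} column (e.g. from \code{\link{readSamFlags}}).
#' @return Named integer vector: n_total, n_mapped.
#' @export
#' @examples
#' countReads(c(0L, 4L, 2048L, 256L))  # total 2, mapped 1
countReads <- function(flags) {
  if (is.data.frame(flags)) flags <- flags$flag
  stopifnot(is.numeric(flags), all(flags >= 0))
  flags <- as.integer(flags)
  primary <- bitwAnd(flags, FLAG_SECONDARY) == 0L &
    bitwAnd(flags, FLAG_SUPPLEMENTARY) == 0L
  mapped <- primary & bitwAnd(flags, FLAG_UNMAPPED) == 0L
  c(n_total = sum(primary), n_mapped = sum(mapped))
}

#' Per-individual mapping fractions
#'
#' @param urReads data.frame of SAM-flag records with columns individual,
#'   flag (and target_id).
#' @param sampleSheet Optional data.frame (individual, population) to attach
#'   population labels.
#' @return data.frame: individual, population (NA when no sheet), n_total,
#'   n_mapped, fraction.
#' @export
mappingFractions <- function(urReads, sampleSheet = NULL) {
  stopifnot(all(c("individual", "flag") %in% colnames(urReads)))
  ids <- unique(urReads$individual)
  rows <- lapply(ids, function(id) {
    ct <- countReads(urReads$flag[urReads$individual == id])
    data.frame(individual = id, n_total = ct[["n_total"]],
               n_mapped = ct[["n_mapped"]],
               fraction = if (ct[["n_total"]] > 0)
                 ct[["n_mapped"]] / ct[["n_total"]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$population <- if (!is.null(sampleSheet))
    sampleSheet$population[match(out$individual, sampleSheet$individual)]
  else NA_character_
  out[, c("individual", "population", "n_total", "n_mapped", "fraction")]
}

#' Allele-frequency depletion curve
#'
#' Fraction of mapped unmapped-reads remaining after removing NS clusters
#' with allele frequency below each threshold. Each mapped read is assigned
#' to exactly one cluster (its primary alignment target); the denominator
#' (all mapped reads) is fixed across thresholds, the comparison is
#' boundary-inclusive (AF >= t), so the curve starts at 1 for t = 0 and is
#' non-increasing.
#'
#' @param readClusters Character vector: the cluster id of each mapped read.
#' @param clusterAfs Named numeric vector of cluster allele frequencies.
#' @param thresholds Minimum-AF thresholds (default the six-value set
#'   0.005, 0.01, 0.025, 0.05, 0.075, 0.10).
#' @return data.frame(threshold, remaining_fraction), including a leading
#'   threshold-0 row.
#' @export
depletionCurve <- function(readClusters, clusterAfs,
                           thresholds = c(0.005, 0.01, 0.025, 0.05, 0.075,
                                          0.10)) {
  stopifnot(length(readClusters) > 0L)
  unknown <- setdiff(unique(readClusters), names(clusterAfs))
  if (length(unknown) > 0L)
    stop("read assigned to unknown cluster: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  af <- clusterAfs[readClusters]
  th <- sort(unique(c(0, thresholds)))
  data.frame(threshold = th,
             remaining_fraction = vapply(th, function(t) mean(af >= t), 0))
}

#' Compare mapping fractions between two references
#'
#' Two-sided Mann-Whitney U test of the per-individual mapping fractions
#' against reference A versus reference B: exact for small samples (at most
#' 20 observations in total, no ties), normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param fractionsA,fractionsB Numeric vectors of per-individual fractions.
#' @return list(p_value, U, exact).
#' @export
#' @examples
#' compareTwoReferences(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
compareTwoReferences <- function(fractionsA, fractionsB) {
  stopifnot(length(fractionsA) > 0L, length(fractionsB) > 0L)
  nTot <- length(fractionsA) + length(fractionsB)
  exact <- nTot <= 20L && !anyDuplicated(c(fractionsA, fractionsB))
  wt <- stats::wilcox.test(fractionsA, fractionsB, exact = exact,
                           correct = TRUE, alternative = "two.sided")
  list(p_value = wt$p.value, U = unname(wt$statistic), exact = exact)
}

#' One-way ANOVA with Tukey HSD across populations
#'
#' Fixed-effects one-way ANOVA of a response (e.g. mapping fraction or
#' remaining fraction at one AF threshold) across population groups,
#' followed by Tukey's honestly-significant-difference test on all pairs
#' (studentized-range distribution).
#'
#' @param values Numeric response values.
#' @param groups Group labels (same length).
#' @return list(F, p_value, tukey): the ANOVA F statistic and p-value, and a
#'   data.frame of pairwise comparisons (pair, diff, p_adj).
#' @export
populationAnovaTukey <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 observations")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Cross-population depletion statistics
#'
#' For each AF threshold, one-way ANOVA + Tukey HSD of the per-individual
#' remaining fractions across populations (the cross-population
#' depletion-comparison table).
#'
#' @param curves data.frame with columns individual, population, threshold,
#'   remaining_fraction (one row per individual and threshold).
#' @param thresholds Thresholds to test (default: all nonzero ones present).
#' @return data.frame with one row per (threshold, pair): threshold, F,
#'   anova_p, pair, tukey_p.
#' @export
depletionAnova <- function(curves, thresholds = NULL) {
  stopifnot(all(c("individual", "population", "threshold",
                  "remaining_fraction") %in% colnames(curves)))
  if (is.null(thresholds))
    thresholds <- sort(setdiff(unique(curves$threshold), 0))
  rows <- lapply(thresholds, function(t) {
    g <- curves[curves$threshold == t, , drop = FALSE]
    at <- populationAnovaTukey(g$remaining_fraction, g$population)
    data.frame(threshold = t, F = at$F, anova_p = at$p_value,
               pair = at$tukey$pair, tukey_p = at$tukey$p_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
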