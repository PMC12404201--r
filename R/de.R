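# Differential circRNA expression: logCPM, a conditional binomial exact
# test on pooled group counts, and threshold-based classification into
# neuronal / nonneuronal and mutant-affected groups.

#' Log2 counts per million with a 0.5 prior count
#'
#' `log2((count + 0.5) / (lib_size + 1) * 1e6)`.
#'
#' @param count nonnegative counts (vectorised).
#' @param lib_size positive library sizes.
#' @return numeric logCPM values.
#' @export
log_cpm <- function(count, lib_size) {
  if (any(lib_size <= 0)) stop("lib_size must be positive")
  log2((count + 0.5) / (lib_size + 1) * 1e6)
}

#' Conditional binomial exact test for a two-group count contrast
#'
#' Given `n = countA + countB`, `countA ~ Binomial(n, libA/(libA+libB))`
#' under the null of equal rates; the two-sided p-value sums outcome
#' probabilities no larger than the observed one. The fold change uses 0.5
#' prior counts: `log2(((countA+0.5)/libA) / ((countB+0.5)/libB))`.
#'
#' @param countA,countB nonnegative counts.
#' @param libA,libB positive library sizes.
#' @return list with `log2FC` and `p`. Both counts zero gives `p = 1`,
#'   `log2FC` per the prior-count formula (0 for equal libraries).
#' @export
exact_rate_test <- function(countA, libA, countB, libB) {
  if (countA < 0 || countB < 0) stop("counts must be nonnegative")
  if (libA <= 0 || libB <= 0) stop("library sizes must be positive")
  lfc <- log2(((countA + 0.5) / libA) / ((countB + 0.5) / libB))
  n <- countA + countB
  p <- if (n == 0) 1 else binom.test(countA, n, libA / (libA + libB))$p.value
  list(log2FC = lfc, p = p)
}

#' Differential circRNA expression between two groups
#'
#' Replicates are combined by summing counts (and library sizes) within
#' each group before testing each circRNA with [exact_rate_test()].
#' `logCPM` is the mean of the two group-level logCPM values.
#'
#' @param counts data frame with `circ_id, sample_id, group, bsj`; `group`
#'   must have exactly two levels. The first level (alphabetical, or factor
#'   order) is the "A" side of the contrast.
#' @param lib_sizes optional named (by `sample_id`) vector of library
#'   sizes; defaults to each sample's total BSJ count.
#' @return data frame `circ_id, countA, countB, logCPM, log2FC, p`.
#' @export
circ_de <- function(counts, lib_sizes = NULL) {
  groups <- if (is.factor(counts$group)) levels(counts$group)
            else sort(unique(counts$group))
  if (length(groups) != 2L) stop("exactly two groups required")
  if (is.null(lib_sizes)) {
    lib_sizes <- tapply(counts$bsj, counts$sample_id, sum)
  }
  sample_group <- unique(counts[, c("sample_id", "group")])
  libA <- sum(lib_sizes[sample_group$sample_id[sample_group$group == groups[1]]])
  libB <- sum(lib_sizes[sample_group$sample_id[sample_group$group == groups[2]]])
  cA <- tapply(counts$bsj[counts$group == groups[1]],
               counts$circ_id[counts$group == groups[1]], sum)
  cB <- tapply(counts$bsj[counts$group == groups[2]],
               counts$circ_id[counts$group == groups[2]], sum)
  ids <- sort(union(names(cA), names(cB)))
  a <- ifelse(ids %in% names(cA), cA[ids], 0)
  b <- ifelse(ids %in% names(cB), cB[ids], 0)
  res <- mapply(function(x, y) exact_rate_test(x, libA, y, libB), a, b,
                SIMPLIFY = FALSE)
  data.frame(
    circ_id = ids, countA = as.integer(a), countB = as.integer(b),
    logCPM = (log_cpm(a, libA) + log_cpm(b, libB)) / 2,
    log2FC = vapply(res, `[[`, numeric(1), "log2FC"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classification threshold presets
#'
#' Named threshold sets used by [classify_circ()]: the population contrast
#' (`logCPM > -5`, `p < 0.1`, `|log2FC| > 0`), a stricter display variant
#' (`p < 0.05`, `logCPM > -5.4`, `|log2FC| >= 1`), and the mutant contrasts
#' (`|log2FC| >= 0.5` single mutant, `>= 0.3` double mutant, both with
#' `logCPM > -5.4`).
#'
#' @return named list of threshold lists.
#' @export
de_presets <- function() {
  list(
    population = list(logcpm_floor = -5, p_max = 0.1, lfc_min = 0,
                      lfc_strict = TRUE),
    population_display = list(logcpm_floor = -5.4, p_max = 0.05, lfc_min = 1,
                              lfc_strict = FALSE),
    mutant_elav = list(logcpm_floor = -5.4, lfc_min = 0.5),
    mutant_elav_fne = list(logcpm_floor = -5.4, lfc_min = 0.3)
  )
}

#' Classify circRNAs by contrast thresholds
#'
#' Population contrast: `neuronal` when logCPM, p and a positive log2FC
#' pass the preset thresholds; `nonneuronal` for a passing negative
#' log2FC; `other` otherwise. Mutant contrasts (log2FC of mutant over
#' wild type): `elav_down` / `elav_up` when `|log2FC|` reaches the preset
#' minimum and the expression floor is met; `unchanged` otherwise.
#'
#' @param results data frame from [circ_de()].
#' @param contrast one of `"population"`, `"population_display"`,
#'   `"mutant_elav"`, `"mutant_elav_fne"`.
#' @return `results` with a `label` column.
#' @export
classify_circ <- function(results, contrast = "population") {
  presets <- de_presets()
  if (!contrast %in% names(presets)) stop("unknown contrast: ", contrast)
  th <- presets[[contrast]]
  floor_ok <- results$logCPM > th$logcpm_floor
  if (startsWith(contrast, "population")) {
    p_ok <- results$p < th$p_max
    pass_up <- if (isTRUE(th$lfc_strict)) results$log2FC > th$lfc_min
               else results$log2FC >= th$lfc_min
    pass_dn <- if (isTRUE(th$lfc_strict)) results$log2FC < -th$lfc_min
               else results$log2FC <= -th$lfc_min
    label <- rep("other", nrow(results))
    label[floor_ok & p_ok & pass_up] <- "neuronal"
    label[floor_ok & p_ok & pass_dn] <- "nonneuronal"
  } else {
    label <- rep("unchanged", nrow(results))
    label[floor_ok & results$log2FC >= th$lfc_min] <- "elav_up"
    label[floor_ok & results$log2FC <= -th$lfc_min] <- "elav_down"
  }
  results$label <- label
  results
}
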