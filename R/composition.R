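#' Published composition of the five HNSCC study cohorts
#'
#' The published clinical/pathological composition table for the five
#' head-and-neck squamous cell carcinoma cohorts the workflow targets
#' (TCGA, Leipzig/GSE65858, FHCRC/GSE41613, MDACC/GSE42743, KHUMC):
#' per-cohort counts and printed percentages for age, sex, stage, and the
#' LR/HR risk-subgroup split. The `percent` column is kept as the printed
#' string so its decimal precision is known.
#'
#' @return data.frame with `cohort`, `n_cohort`, `characteristic`,
#'   `category`, `count`, `percent` (character).
#' @export
cohort_composition <- function() {
  path <- system.file("extdata", "cohort_composition.tsv",
                      package = "fatsig")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(percent = "character"))
}

#' Arithmetic consistency of a cohort-composition table
#'
#' Recomputes each percentage as `100 * count / n_cohort` and compares it
#' with the printed value at the printed decimal precision; also checks
#' that the counts of each fully-enumerated characteristic sum to the
#' cohort size.
#'
#' @param comp composition table, default [cohort_composition()].
#' @return list with `rows` (per-row recomputed percent, absolute error,
#'   printed-precision tolerance and pass flag) and `sums` (per cohort and
#'   characteristic: count total, cohort n, pass flag).
#' @export
check_composition <- function(comp = cohort_composition()) {
  printed <- as.numeric(comp$percent)
  decimals <- vapply(strsplit(comp$percent, ".", fixed = TRUE),
                     function(p) if (length(p) > 1L) nchar(p[2L]) else 0L,
                     integer(1))
  recomputed <- 100 * comp$count / comp$n_cohort
  tol <- 0.5 * 10^(-decimals) + 1e-9
  rows <- data.frame(
    comp[, c("cohort", "characteristic", "category", "count", "n_cohort")],
    printed = printed,
    recomputed = recomputed,
    abs_error = abs(recomputed - printed),
    tol = tol,
    ok = abs(recomputed - printed) <= tol
  )
  agg <- stats::aggregate(count ~ cohort + characteristic + n_cohort,
                          data = comp, FUN = sum)
  agg$ok <- agg$count == agg$n_cohort
  list(rows = rows, sums = agg)
}
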