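#' Per-gene fold change and Student t statistics between mutation groups
#'
#' For every gene, computes the log2 fold change (mean over mutated minus
#' mean over wild-type samples of the log2 matrix), the linear fold change
#' `2^log2fc`, and a two-sample Student t test. The default is the
#' pooled-variance t with `n_mut + n_wt - 2` degrees of freedom; Welch's
#' unequal-variance t is available via `welch = TRUE`. Genes with zero
#' pooled variance are flagged (`degenerate = TRUE`) and carry NA
#' statistics; callers exclude them from selection.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param mutation data.frame with `sample_id`, `mutated` covering the
#'   matrix columns.
#' @param welch use Welch's t instead of pooled-variance Student t.
#' @return data.frame with `gene_id`, `fc`, `log2fc`, `t_stat`, `t_p`,
#'   `n_mut`, `n_wt`, `degenerate`.
#' @export
gene_group_stats <- function(expr, mutation, welch = FALSE) {
  mut <- mutation$mutated[match(colnames(expr), mutation$sample_id)]
  if (anyNA(mut)) stop("mutation status missing for some expression samples")
  n1 <- sum(mut == 1L)
  n0 <- sum(mut == 0L)
  if (n1 < 2L || n0 < 2L) {
    stop("both mutation groups need >= 2 samples (mutated: ", n1,
         ", wild-type: ", n0, ")")
  }
  x1 <- expr[, mut == 1L, drop = FALSE]
  x0 <- expr[, mut == 0L, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  log2fc <- m1 - m0
  if (welch) {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2L, nrow(expr))
  }
  degenerate <- se == 0 | !is.finite(se)
  t_stat <- ifelse(degenerate, NA_real_, log2fc / se)
  t_p <- ifelse(degenerate, NA_real_,
                2 * stats::pt(-abs(t_stat), df = df))
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with zero pooled variance flagged as degenerate")
  }
  data.frame(gene_id = rownames(expr), fc = 2^log2fc, log2fc = log2fc,
             t_stat = t_stat, t_p = t_p,
             n_mut = n1, n_wt = n0, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene Pearson correlation with the anchor gene
#'
#' Pearson correlation of each gene's expression with the anchor gene
#' across all samples, with the two-sided p-value from the exact t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. The
#' anchor's own row is reported with `r = 1` but flagged ineligible;
#' constant genes are flagged degenerate.
#'
#' @param expr log2 expression matrix, genes x samples (>= 3 samples).
#' @param anchor anchor gene ID, must be a row of `expr`.
#' @return data.frame with `gene_id`, `r`, `r_p`, `degenerate`.
#' @export
anchor_correlation <- function(expr, anchor) {
  if (!anchor %in% rownames(expr)) {
    stop("anchor gene '", anchor, "' not present in expression matrix")
  }
  n <- ncol(expr)
  if (n < 3L) stop("anchor correlation needs >= 3 samples")
  a <- expr[anchor, ]
  a_c <- a - mean(a)
  ssa <- sum(a_c^2)
  if (ssa == 0) stop("anchor gene is constant; correlation undefined")
  x_c <- expr - rowMeans(expr)
  ssx <- rowSums(x_c^2)
  r <- as.vector(x_c %*% a_c) / sqrt(ssx * ssa)
  degenerate <- ssx == 0
  r[degenerate] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tval <- r * sqrt((n - 2L) / pmax(1 - r^2, .Machine$double.eps))
  r_p <- 2 * stats::pt(-abs(tval), df = n - 2L)
  r_p[degenerate] <- NA_real_
  if (any(degenerate)) {
    warning(sum(degenerate), " constant gene(s) flagged as degenerate")
  }
  data.frame(gene_id = rownames(expr), r = r, r_p = r_p,
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default selection thresholds
#'
#' Fold change >= 1.5, t-test p < 0.05, |r| > 0.2, correlation p < 0.05.
#' No multiple-testing correction is applied by default (raw p-values);
#' [select_signature()] offers an optional BH-FDR mode.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(fc_min = 1.5, t_p_max = 0.05, r_abs_min = 0.2, r_p_max = 0.05)
}

#' Select the anchor-coupled signature gene set
#'
#' A gene enters the signature when it satisfies all four criteria:
#' fold change (direction-agnostic by default, `max(fc, 1/fc) >= fc_min`),
#' Student t-test p below `t_p_max`, absolute Pearson correlation with the
#' anchor above `r_abs_min`, and correlation p below `r_p_max`. The anchor
#' itself and degenerate genes are excluded; output is ordered by gene ID.
#'
#' @param expr log2 expression matrix, genes x samples (aligned).
#' @param mutation mutation data.frame (`sample_id`, `mutated`).
#' @param anchor anchor gene ID.
#' @param thresholds list as from [default_thresholds()].
#' @param fc_directional require `fc >= fc_min` (up-regulated only) rather
#'   than the direction-agnostic criterion.
#' @param fdr apply Benjamini-Hochberg adjustment to both p-values before
#'   thresholding.
#' @param welch passed to [gene_group_stats()].
#' @return `fatsig_signature`: list with `anchor_gene`, `thresholds`, and
#'   `genes`, a data.frame of per-gene statistics for the selected genes.
#' @export
select_signature <- function(expr, mutation, anchor,
                             thresholds = default_thresholds(),
                             fc_directional = FALSE, fdr = FALSE,
                             welch = FALSE) {
  stopifnot(all(c("fc_min", "t_p_max", "r_abs_min", "r_p_max") %in%
                  names(thresholds)))
  gs <- gene_group_stats(expr, mutation, welch = welch)
  ac <- anchor_correlation(expr, anchor)
  stats_df <- merge(gs, ac, by = "gene_id", sort = FALSE)
  stats_df$degenerate <- stats_df$degenerate.x | stats_df$degenerate.y
  stats_df$degenerate.x <- stats_df$degenerate.y <- NULL

  t_p <- stats_df$t_p
  r_p <- stats_df$r_p
  if (fdr) {
    t_p <- stats::p.adjust(t_p, method = "BH")
    r_p <- stats::p.adjust(r_p, method = "BH")
  }
  fc_eff <- if (fc_directional) {
    stats_df$fc
  } else {
    pmax(stats_df$fc, 1 / stats_df$fc)
  }
  keep <- !stats_df$degenerate &
    stats_df$gene_id != anchor &
    fc_eff >= thresholds$fc_min &
    t_p < thresholds$t_p_max &
    abs(stats_df$r) > thresholds$r_abs_min &
    r_p < thresholds$r_p_max
  genes <- stats_df[keep, c("gene_id", "fc", "log2fc", "t_stat", "t_p",
                            "r", "r_p", "n_mut", "n_wt")]
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(anchor_gene = anchor,
                 thresholds = thresholds[c("fc_min", "t_p_max",
                                           "r_abs_min", "r_p_max")],
                 genes = genes),
            class = "fatsig_signature")
}

#' @export
print.fatsig_signature <- function(x, ...) {
  cat("Signature of", nrow(x$genes), "genes coupled to anchor",
      x$anchor_gene, "\n")
  cat(sprintf("thresholds: FC >= %g, t p < %g, |r| > %g, r p < %g\n",
              x$thresholds$fc_min, x$thresholds$t_p_max,
              x$thresholds$r_abs_min, x$thresholds$r_p_max))
  invisible(x)
}
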