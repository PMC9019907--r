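#' Centered correlation distance between two profiles
#'
#' `1 - r`, with `r` the standard (mean-centered) Pearson correlation —
#' the Cluster 3.0 "correlation (centered)" similarity turned into a
#' distance. Ranges over [0, 2]; invariant to positive-affine transforms
#' of either profile.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return distance in [0, 2].
#' @export
centered_correlation_distance <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("profiles must have equal length >= 3")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant profile: centered correlation undefined")
  }
  1 - stats::cor(a, b)
}

# Pairwise centered-correlation distance between sample columns.
.sample_cor_dist <- function(expr) {
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample profile(s): ",
         paste(utils::head(colnames(expr)[sds == 0], 5L), collapse = ", "))
  }
  d <- 1 - stats::cor(expr)
  d[d < 0] <- 0  # guard rounding below zero
  d
}

#' Hierarchical clustering of samples on signature-gene expression
#'
#' Agglomerative complete-linkage clustering under the centered-correlation
#' distance, with a deterministic tie-break: among pairs at the minimal
#' distance, the pair whose (smallest member ID, then partner's smallest
#' member ID) is lexicographically first is merged. This makes the result
#' invariant to the input column order. By default genes are z-scored
#' (row-normalized) before clustering, matching the usual heatmap
#' convention; set `zscore = FALSE` for raw-scale clustering.
#'
#' @param expr expression matrix restricted to signature genes
#'   (genes x samples), >= 2 genes and >= 2 samples.
#' @param zscore z-score each gene across samples first; zero-variance
#'   genes are dropped with a warning.
#' @return an object of class `c("fatsig_dendrogram", "hclust")` with the
#'   standard `merge`, `height`, `labels`, `order` components.
#' @export
cluster_samples <- function(expr, zscore = TRUE) {
  if (ncol(expr) < 2L) stop("clustering needs >= 2 samples")
  if (nrow(expr) < 2L) stop("clustering needs >= 2 signature genes")
  if (zscore) {
    sds <- apply(expr, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("dropped ", sum(sds == 0), " zero-variance gene(s)")
      expr <- expr[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
      if (nrow(expr) < 2L) stop("fewer than 2 non-degenerate genes")
    }
    expr <- (expr - rowMeans(expr)) / sds
  }
  d <- .sample_cor_dist(expr)
  .complete_linkage(d)
}

# Deterministic complete-linkage agglomeration on a distance matrix whose
# dimnames are the sample IDs.
.complete_linkage <- function(d) {
  n <- ncol(d)
  ids <- colnames(d)
  stopifnot(!is.null(ids), n >= 2L)
  # active cluster bookkeeping: node (hclust coding), smallest member ID
  node <- -seq_len(n)
  rep_id <- ids
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  dm <- d
  diag(dm) <- Inf
  dm[!upper.tri(dm)] <- Inf
  work <- d
  diag(work) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 1e-12 * max(1, abs(dmin)), arr.ind = TRUE)
    # deterministic tie-break on the pair's smallest member IDs
    keys <- t(apply(cand, 1L, function(rc) {
      sort(c(rep_id[idx[rc[1L]]], rep_id[idx[rc[2L]]]))
    }))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- work[i, j]
    # complete linkage: new cluster distance = max of the two
    newd <- pmax(work[i, ], work[j, ])
    work[i, ] <- newd
    work[, i] <- newd
    work[i, i] <- Inf
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
    node[i] <- step
    rep_id[i] <- min(rep_id[i], rep_id[j])
  }
  out <- list(merge = merge, height = height,
              order = .dendro_order(merge, n),
              labels = ids, method = "complete",
              dist.method = "centered_correlation",
              call = match.call())
  class(out) <- c("fatsig_dendrogram", "hclust")
  out
}

# leaf order for plotting: left-to-right traversal of the merge tree
.dendro_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram into the two top-level clusters
#'
#' Removes the final merge; the two remaining subtrees are the clusters.
#'
#' @param dend a dendrogram from [cluster_samples()].
#' @return list of two character vectors of sample IDs (each sorted).
#' @export
cut_two <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (n < 2L) stop("need >= 2 leaves")
  members <- function(node) {
    if (node < 0L) return(dend$labels[-node])
    c(members(dend$merge[node, 1L]), members(dend$merge[node, 2L]))
  }
  top <- dend$merge[n - 1L, ]
  lapply(seq_len(2L), function(k) sort(members(top[k])))
}

#' Assign low-/high-risk labels to a two-cluster partition
#'
#' The cluster with the higher anchor-mutation rate is labeled `HR`; if the
#' rates are exactly equal, the cluster with the higher mean anchor
#' expression is `HR`; if still tied, the larger cluster is `HR`. The rule
#' that fired is recorded in the `labeling_basis` attribute.
#'
#' @param partition list of two sample-ID vectors from [cut_two()].
#' @param mutation mutation data.frame (`sample_id`, `mutated`).
#' @param expr expression matrix containing the anchor row.
#' @param anchor anchor gene ID.
#' @return data.frame with `sample_id`, `risk` (`"LR"`/`"HR"`),
#'   `provenance = "clustered"`; attribute `labeling_basis` in
#'   `c("mutation_rate", "anchor_expression", "size")`.
#' @export
assign_risk_labels <- function(partition, mutation, expr, anchor) {
  stopifnot(length(partition) == 2L,
            all(lengths(partition) > 0L))
  rate <- vapply(partition, function(ids) {
    mean(mutation$mutated[match(ids, mutation$sample_id)])
  }, numeric(1))
  if (anyNA(rate)) stop("mutation status missing for some cluster members")
  if (rate[1L] != rate[2L]) {
    hr <- which.max(rate)
    basis <- "mutation_rate"
  } else {
    amean <- vapply(partition, function(ids) {
      mean(expr[anchor, ids])
    }, numeric(1))
    if (amean[1L] != amean[2L]) {
      hr <- which.max(amean)
      basis <- "anchor_expression"
    } else {
      hr <- which.max(lengths(partition))
      basis <- "size"
    }
  }
  labels <- data.frame(
    sample_id = c(partition[[1L]], partition[[2L]]),
    risk = c(rep(if (hr == 1L) "HR" else "LR", length(partition[[1L]])),
             rep(if (hr == 2L) "HR" else "LR", length(partition[[2L]]))),
    provenance = "clustered",
    stringsAsFactors = FALSE
  )
  labels <- labels[order(labels$sample_id), , drop = FALSE]
  rownames(labels) <- NULL
  attr(labels, "labeling_basis") <- basis
  labels
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert-Arabie adjusted Rand index; used to score recovered
#' patient partitions against planted subgroup truth.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
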