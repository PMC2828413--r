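#' Uncentered-correlation distance between samples
#'
#' The Eisen clustering convention: similarity
#' s(x, y) = (1/n) sum_i (x_i / s0_x)(y_i / s0_y) with
#' s0_v = sqrt((1/n) sum_i v_i^2) — a cosine-like measure that assumes a
#' zero reference level instead of centering. Distance is d = 1 - s, in
#' \[0, 2\], with d(x, x) = 0. Computed between samples (columns), usually
#' on the matrix restricted to the signature features.
#'
#' @param x expression matrix, features x samples.
#' @return symmetric sample-by-sample distance matrix.
#' @export
uncentered_correlation_distance <- function(x) {
  validate_expression(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  rms <- sqrt(colMeans(x^2))
  if (any(rms == 0))
    stop("all-zero sample vector(s): ", paste(colnames(x)[rms == 0], collapse = ", "))
  xn <- sweep(x, 2L, rms, "/")
  s <- crossprod(xn) / nrow(x)
  d <- 1 - s
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) agglomeration with deterministic tie-breaks
#'
#' Repeatedly merges the pair of clusters with minimal average pairwise
#' inter-cluster distance; the recorded merge height is that average.
#' Exact ties are broken by the lexicographically smallest pair of cluster
#' indices in creation order (original leaves first, then merge products),
#' so runs are fully deterministic. Heights are not forced to be
#' monotone — average linkage on correlation distances can invert.
#'
#' @param d symmetric, zero-diagonal, finite distance matrix with sample
#'   identifiers as dimnames.
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
average_linkage <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance must be a square matrix")
  if (!all(is.finite(d))) stop("distance matrix must be finite")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples")
  labels <- if (!is.null(rownames(d))) rownames(d) else as.character(seq_len(n))

  # Active clusters kept in creation order; hclust codes: -leaf or +merge row.
  dm <- d
  code <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- nrow(dm)
    ut <- upper.tri(dm)
    mn <- min(dm[ut])
    cand <- which(dm == mn & ut, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- mn
    # Weighted Lance-Williams update = average of all original cross pairs.
    new_row <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    code <- c(code[keep], step)
    size <- c(size[keep], size[i] + size[j])
  }
  hc <- list(merge = merge, height = height,
             order = dendrogram_leaf_order(merge),
             labels = labels, method = "average",
             call = match.call(), dist.method = "uncentered correlation")
  class(hc) <- "hclust"
  hc
}

# Leaf order by depth-first traversal of the merge table (root last).
dendrogram_leaf_order <- function(merge) {
  leaves_of <- function(node) {
    if (node < 0L) return(-node)
    c(leaves_of(merge[node, 1L]), leaves_of(merge[node, 2L]))
  }
  leaves_of(nrow(merge))
}

# Sample indices under each child of the root merge.
root_split <- function(hc) {
  merge <- hc$merge
  leaves_of <- function(node) {
    if (node < 0L) return(-node)
    c(leaves_of(merge[node, 1L]), leaves_of(merge[node, 2L]))
  }
  root <- nrow(merge)
  list(leaves_of(merge[root, 1L]), leaves_of(merge[root, 2L]))
}

#' Cut a dendrogram into high- and low-anchor clusters
#'
#' Removes the final (root) merge, yielding two sample clusters, and
#' labels the cluster with the higher mean anchor expression `HSC`
#' (high-anchor cluster) and the other `LSC`.
#'
#' @param hc dendrogram from [average_linkage()].
#' @param x expression matrix containing the anchor feature and the
#'   clustered samples.
#' @param anchor_id anchor feature identifier.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (factor HSC/LSC named by sample), `anchor_means` (named numeric) and
#'   `dendrogram`.
#' @export
cut_two <- function(hc, x, anchor_id) {
  stopifnot(inherits(hc, "hclust"))
  validate_expression(x)
  if (!anchor_id %in% rownames(x)) stop("anchor feature not found: ", anchor_id)
  halves <- root_split(hc)
  ids <- lapply(halves, function(idx) hc$labels[idx])
  missing <- setdiff(unlist(ids), colnames(x))
  if (length(missing)) stop("samples in dendrogram absent from matrix: ",
                            paste(missing, collapse = ", "))
  means <- vapply(ids, function(s) mean(x[anchor_id, s]), numeric(1L))
  if (means[1L] == means[2L])
    stop("anchor means exactly equal between the two subtrees; manual labelling required")
  hi <- which.max(means)
  labels <- setNames(rep("LSC", length(unlist(ids))), unlist(ids))
  labels[ids[[hi]]] <- "HSC"
  labels <- factor(labels, levels = c("HSC", "LSC"))
  structure(list(labels = labels[hc$labels],
                 anchor_means = c(HSC = means[hi], LSC = means[-hi]),
                 dendrogram = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat("cluster_assignment: HSC =", tab[["HSC"]], "samples (mean anchor",
      signif(x$anchor_means[["HSC"]], 4), "), LSC =", tab[["LSC"]],
      "samples (mean anchor", signif(x$anchor_means[["LSC"]], 4), ")\n")
  invisible(x)
}
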