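## t-SNE embedding, complete-linkage sub-type clustering, and differential
## reaction sets between sub-type clusters.

#' t-SNE embedding of a precomputed distance matrix
#'
#' Deterministic under a fixed seed. The perplexity defaults to
#' `min(30, floor((n - 1) / 3))` and must satisfy `perplexity < (n - 1) / 3`.
#'
#' @param d an [org_dist()].
#' @param perplexity t-SNE perplexity (effective neighborhood size).
#' @param seed RNG seed governing the embedding initialization.
#' @param max_iter gradient-descent iterations.
#' @return a `tsne_result` with 2-D `coordinates`, `perplexity` and `seed`.
#' @export
tsne_embed <- function(d, perplexity = NULL, seed = 42, max_iter = 1000) {
  stopifnot(inherits(d, "org_dist"))
  n <- nrow(d$values)
  if (is.null(perplexity)) perplexity <- min(30, floor((n - 1) / 3))
  if (!is_number(perplexity) || perplexity < 1 || 3 * perplexity >= n - 1)
    stop_validation("tsne_embed: perplexity %s is invalid for %d organisms (need 1 <= perplexity < (n-1)/3)",
                    format(perplexity), n)
  coords <- with_local_seed(seed, {
    Rtsne::Rtsne(stats::as.dist(d$values), is_distance = TRUE,
                 dims = 2, perplexity = perplexity, theta = 0,
                 max_iter = max_iter, verbose = FALSE)$Y
  })
  dimnames(coords) <- list(rownames(d$values), c("tsne1", "tsne2"))
  structure(list(coordinates = coords, perplexity = perplexity, seed = seed),
            class = "tsne_result")
}

#' Complete-linkage hierarchical clustering cut at k clusters
#'
#' Cluster ids 1..k are assigned deterministically: by decreasing cluster
#' size, ties broken by the lexicographically smallest member.
#'
#' @param d an [org_dist()].
#' @param k number of clusters, `2 <= k <= n`.
#' @return a `cluster_assignment`: named integer `labels`, `k`, `linkage`,
#'   and the underlying `hclust` tree.
#' @export
hcluster <- function(d, k) {
  stopifnot(inherits(d, "org_dist"))
  n <- nrow(d$values)
  if (!is_count(k, min = 2) || k > n)
    stop_validation("hcluster: k must satisfy 2 <= k <= %d (got %s)", n, format(k))
  hc <- stats::hclust(stats::as.dist(d$values), method = "complete")
  raw <- stats::cutree(hc, k = k)
  ## deterministic relabeling
  sizes <- table(raw)
  smallest <- vapply(names(sizes), function(cl)
    min(names(raw)[raw == as.integer(cl)]), character(1))
  ord <- order(-as.integer(sizes), smallest)
  relab <- stats::setNames(seq_len(k), names(sizes)[ord])
  labels <- stats::setNames(unname(relab[as.character(raw)]), names(raw))
  structure(list(labels = labels, k = k, linkage = "complete", hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d organisms in %d complete-linkage clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(as.integer(table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Differential features between two sub-type clusters
#'
#' A feature is A-specific when its presence fraction is at least `hi` in
#' cluster A and at most `lo` in cluster B (and symmetrically B-specific).
#' The table is sorted by the presence-fraction gap.
#'
#' @param profiles a [binary_profile()] covering the clustered organisms.
#' @param clusters a [hcluster()] assignment.
#' @param a,b distinct cluster ids.
#' @param hi,lo presence-fraction thresholds.
#' @return data.frame with `feature`, `frac_a`, `frac_b`, `direction`
#'   (`"A-specific"`/`"B-specific"`), and `gap`.
#' @export
subtype_contrast <- function(profiles, clusters, a, b, hi = 0.9, lo = 0.1) {
  stopifnot(inherits(profiles, "binary_profile"),
            inherits(clusters, "cluster_assignment"))
  if (identical(a, b)) stop_validation("subtype_contrast: clusters a and b must differ")
  for (cl in c(a, b)) {
    if (!cl %in% clusters$labels)
      stop_validation("subtype_contrast: unknown cluster id '%s'", format(cl))
  }
  orgs_a <- names(clusters$labels)[clusters$labels == a]
  orgs_b <- names(clusters$labels)[clusters$labels == b]
  miss <- setdiff(c(orgs_a, orgs_b), rownames(profiles$values))
  if (length(miss))
    stop_validation("subtype_contrast: organisms missing from profiles: %s",
                    paste(miss, collapse = ", "))
  fa <- colMeans(profiles$values[orgs_a, , drop = FALSE])
  fb <- colMeans(profiles$values[orgs_b, , drop = FALSE])
  a_spec <- fa >= hi & fb <= lo
  b_spec <- fb >= hi & fa <= lo
  keep <- a_spec | b_spec
  out <- data.frame(feature = colnames(profiles$values)[keep],
                    frac_a = unname(fa[keep]), frac_b = unname(fb[keep]),
                    direction = ifelse(a_spec[keep], "A-specific", "B-specific"),
                    gap = abs(fa - fb)[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gap, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
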