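## Principal coordinate analysis with discriminative-feature loadings.
##
## Classical scaling: square the distances, double-center -D^2/2, and
## eigendecompose; coordinates are eigenvectors scaled by the square root of
## their (positive) eigenvalues. Axes with nonpositive eigenvalues are
## dropped -- no Cailliez/Lingoes correction -- and their total magnitude is
## reported as negative_eigenvalue_mass, favoring transparency over
## smoothing. Jaccard distances are typically close to Euclidean-embeddable,
## so this mass stays small in practice.

#' Principal coordinate analysis of a distance matrix
#'
#' @param d an [org_dist()].
#' @param n_axes number of axes requested (at least 1; fewer may be
#'   returned if fewer eigenvalues are positive).
#' @return a `pcoa_result` with centered `coordinates` (organisms x axes),
#'   the full `eigenvalues` vector, per-axis `explained_fraction`
#'   (eigenvalue over the sum of positive eigenvalues), and
#'   `negative_eigenvalue_mass`.
#' @export
pcoa <- function(d, n_axes = 2) {
  stopifnot(inherits(d, "org_dist"), is_count(n_axes, min = 1))
  D <- d$values
  n <- nrow(D)
  if (n < n_axes + 1L)
    stop_validation("pcoa: %d organisms cannot support %d axes", n, n_axes)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  k <- min(n_axes, length(pos))
  if (k == 0L) stop_runtime("pcoa: no positive eigenvalues")
  coords <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(rownames(D), paste0("Axis", seq_len(k)))
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    explained_fraction = ev[pos[seq_len(k)]] / sum(ev[pos]),
    negative_eigenvalue_mass = sum(abs(ev[ev < -tol]))),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d organisms, %d axes (%s%% explained), negative mass %.3g\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f", 100 * x$explained_fraction), collapse = "/"),
              x$negative_eigenvalue_mass))
  invisible(x)
}

#' Feature loadings on the first two principal coordinates
#'
#' Each 0/1 feature column is Pearson-correlated (equivalently
#' point-biserial) with the axis-1 and axis-2 coordinates; the relevance
#' score is the Euclidean norm of the two correlations and features are
#' ranked by it, ties broken by feature id. Constant features get relevance
#' 0 and are never selected.
#'
#' @param profiles a [binary_profile()] sharing organisms with `ord`.
#' @param ord a `pcoa_result` with at least two axes.
#' @param top_n how many features to flag as most discriminative.
#' @return data.frame (one row per feature, sorted by rank) with
#'   correlations, `relevance`, `rank`, and a logical `top` column marking
#'   the `top_n` selection.
#' @export
feature_loadings <- function(profiles, ord, top_n = 200) {
  stopifnot(inherits(profiles, "binary_profile"), inherits(ord, "pcoa_result"))
  orgs <- rownames(ord$coordinates)
  if (!setequal(orgs, rownames(profiles$values)))
    stop_validation("feature_loadings: profiles and ordination organisms differ")
  if (ncol(ord$coordinates) < 2L)
    stop_validation("feature_loadings needs at least two ordination axes")
  M <- profiles$values[orgs, , drop = FALSE]
  top_n <- min(top_n, ncol(M))
  ax1 <- ord$coordinates[, 1]; ax2 <- ord$coordinates[, 2]
  sds <- apply(M, 2, stats::sd)
  r1 <- vapply(seq_len(ncol(M)), function(j)
    if (sds[j] == 0) 0 else stats::cor(M[, j], ax1), numeric(1))
  r2 <- vapply(seq_len(ncol(M)), function(j)
    if (sds[j] == 0) 0 else stats::cor(M[, j], ax2), numeric(1))
  relevance <- sqrt(r1^2 + r2^2)
  feats <- colnames(M)
  ord_idx <- order(-relevance, feats)
  rank <- integer(length(feats)); rank[ord_idx] <- seq_along(feats)
  out <- data.frame(feature = feats, cor_axis1 = r1, cor_axis2 = r2,
                    relevance = relevance, rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[ord_idx, , drop = FALSE]
  rownames(out) <- NULL
  out$top <- out$rank <= top_n
  attr(out, "top_n") <- top_n
  out
}
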