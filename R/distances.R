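## Binary profiles and pairwise distance matrices.

PROFILE_KINDS <- c("reaction", "essential_nutrient", "annotation")
DISTANCE_KINDS <- c("metabolic", "phenotypic", "annotation", "phylogenetic")

#' Organisms-by-features presence/absence matrix
#'
#' @param values 0/1 matrix with organism row names and feature column names.
#' @param feature_kind `"reaction"`, `"essential_nutrient"` or `"annotation"`.
#' @export
binary_profile <- function(values, feature_kind = "reaction") {
  feature_kind <- match.arg(feature_kind, PROFILE_KINDS)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("binary_profile requires organism row names and feature column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_validation("binary_profile: duplicate organism or feature ids")
  if (!all(values %in% c(0, 1)))
    stop_validation("binary_profile: values must be 0/1")
  storage.mode(values) <- "integer"
  structure(list(values = values, feature_kind = feature_kind),
            class = "binary_profile")
}

#' @export
print.binary_profile <- function(x, ...) {
  cat(sprintf("<binary_profile> %d organisms x %d %s features (fill %.1f%%)\n",
              nrow(x$values), ncol(x$values), x$feature_kind,
              100 * mean(x$values)))
  invisible(x)
}

#' @export
organism_ids.binary_profile <- function(x) rownames(x$values)

#' Symmetric organism distance matrix
#'
#' @param values symmetric nonnegative matrix with zero diagonal and
#'   organism dimnames; Jaccard-derived kinds are additionally bounded by 1.
#' @param kind `"metabolic"`, `"phenotypic"`, `"annotation"` or
#'   `"phylogenetic"`.
#' @export
org_dist <- function(values, kind) {
  kind <- match.arg(kind, DISTANCE_KINDS)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop_validation("org_dist requires organism dimnames")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8)))
    stop_validation("org_dist: matrix is not symmetric")
  if (any(diag(values) != 0)) stop_validation("org_dist: nonzero diagonal")
  if (any(values < 0)) stop_validation("org_dist: negative distances")
  if (kind != "phylogenetic" && any(values > 1 + 1e-12))
    stop_validation("org_dist: %s distances must be bounded by 1", kind)
  structure(list(values = values, kind = kind), class = "org_dist")
}

#' @export
print.org_dist <- function(x, ...) {
  cat(sprintf("<org_dist> %s, %d organisms, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
organism_ids.org_dist <- function(x) rownames(x$values)

## map profile kind -> distance kind
dist_kind_for <- function(feature_kind) {
  switch(feature_kind,
         reaction = "metabolic",
         essential_nutrient = "phenotypic",
         annotation = "annotation")
}

#' Jaccard distance between binary profiles
#'
#' d(i, j) = 1 - |b_i intersect b_j| / |b_i union b_j| over features scored
#' 1. Two all-zero profiles are identical by convention (distance 0 rather
#' than 0/0).
#'
#' @param profiles a [binary_profile()] with at least two organisms.
#' @return an [org_dist()] whose kind follows the profile's feature kind.
#' @export
jaccard_distance <- function(profiles) {
  stopifnot(inherits(profiles, "binary_profile"))
  M <- profiles$values
  if (nrow(M) < 2L)
    stop_validation("jaccard_distance needs at least 2 organisms")
  inter <- M %*% t(M)
  tot <- rowSums(M)
  un <- outer(tot, tot, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  org_dist(d, dist_kind_for(profiles$feature_kind))
}

#' Read a rooted Newick tree with branch lengths
#'
#' @param path Newick file. The tree must be rooted (a basal bifurcation)
#'   and every edge must carry a length; internal polytomies are accepted.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_validation("tree file does not exist: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_validation(
                     "Newick parse error in %s: %s", path, conditionMessage(e)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_validation("Newick parse error in %s", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop_validation("tree has duplicate leaf name(s): %s",
                    paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                          collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop_validation("tree is missing branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop_validation("tree has negative or non-finite branch lengths")
  if (!ape::is.rooted(tree))
    stop_validation("tree is unrooted; a rooted tree is required")
  invisible(tree)
}

#' Cophenetic (patristic) distances between tree leaves
#'
#' The distance between two leaves is the sum of branch lengths along the
#' path connecting them through their most recent common ancestor.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return an [org_dist()] of kind `"phylogenetic"`, leaves sorted.
#' @export
cophenetic_distance <- function(tree) {
  validate_tree(tree)
  D <- stats::cophenetic(tree)
  o <- sort(rownames(D))
  D <- D[o, o]
  D <- (D + t(D)) / 2
  diag(D) <- 0
  org_dist(D, "phylogenetic")
}

#' Restrict distance matrices and profiles to their common organisms
#'
#' All inputs are subset to the intersection of their organism sets and
#' reordered to one canonical (sorted) order; dropped ids are reported with
#' a message.
#'
#' @param ... [org_dist()] and/or [binary_profile()] objects (optionally
#'   named).
#' @return list of the same objects aligned on the shared organisms.
#' @export
align_organisms <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) && is.null(attr(objs[[1]], "class")))
    objs <- objs[[1]]
  stopifnot(length(objs) >= 1L)
  sets <- lapply(objs, organism_ids)
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0L)
    stop_validation("align_organisms: no organisms shared by all inputs")
  dropped <- sort(unique(unlist(lapply(sets, setdiff, common))))
  if (length(dropped))
    message(sprintf("align_organisms: dropping %d organism(s) absent from some inputs: %s",
                    length(dropped), paste(utils::head(dropped, 10), collapse = ", ")))
  lapply(objs, function(o) {
    if (inherits(o, "org_dist")) org_dist(o$values[common, common], o$kind)
    else if (inherits(o, "binary_profile"))
      binary_profile(o$values[common, , drop = FALSE], o$feature_kind)
    else stop_validation("align_organisms: unsupported object of class %s",
                         paste(class(o), collapse = "/"))
  })
}

#' Write / read a square distance matrix as TSV
#'
#' Header row and first column carry organism ids; values are written with
#' 12 significant digits for diff-stable files.
#' @export
write_dist_tsv <- function(d, path) {
  stopifnot(inherits(d, "org_dist"))
  M <- d$values
  df <- data.frame(organism_id = rownames(M),
                   apply(M, 2, function(col) fmt_num(col)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path, kind) {
  df <- read_tsv_plain(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  org_dist(M, kind)
}

#' Write / read a binary profile matrix as TSV
#' @export
write_profile_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "binary_profile"))
  df <- data.frame(organism_id = rownames(profiles$values),
                   profiles$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path, feature_kind = "reaction") {
  df <- read_tsv_plain(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  binary_profile(M, feature_kind)
}
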