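## Shared fixtures and independent oracles. Oracles are deliberately naive
## (enumeration, brute force) and never call the code paths they check.

## ---- toy models -------------------------------------------------------

# linear chain: A_e --EX/TR--> A_c --> B_c --biomass-->
# rich-medium growth = uptake_limit / b_per_unit
toy_chain_model <- function(b_per_unit = 1, organism_id = "toy_chain") {
  metabolic_model(
    organism_id,
    metabolites = list(metabolite("A_e", compartment = "extracellular"),
                       metabolite("A_c"), metabolite("B_c")),
    reactions = list(
      reaction("EX_A", c(A_e = -1), lower_bound = -1000, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("TR_A", c(A_e = -1, A_c = 1)),
      reaction("CORE", c(A_c = -1, B_c = 1)),
      reaction("biomass", c(B_c = -b_per_unit), is_biomass = TRUE)),
    biomass_reaction_id = "biomass")
}

# two interchangeable substrates A and B feeding the same precursor
two_substrate_model <- function() {
  metabolic_model(
    "toy_redundant",
    metabolites = list(metabolite("A_e", compartment = "extracellular"),
                       metabolite("B_e", compartment = "extracellular"),
                       metabolite("P_c")),
    reactions = list(
      reaction("EX_A", c(A_e = -1), lower_bound = -1000, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("EX_B", c(B_e = -1), lower_bound = -1000, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("USE_A", c(A_e = -1, P_c = 1)),
      reaction("USE_B", c(B_e = -1, P_c = 1)),
      reaction("biomass", c(P_c = -1), is_biomass = TRUE)),
    biomass_reaction_id = "biomass")
}

# growth strictly requires molecular oxygen
oxygen_dependent_model <- function() {
  metabolic_model(
    "toy_aerobe",
    metabolites = list(metabolite("A_e", compartment = "extracellular"),
                       metabolite("o2_e", compartment = "extracellular"),
                       metabolite("A_c"), metabolite("o2_c"), metabolite("P_c")),
    reactions = list(
      reaction("EX_A", c(A_e = -1), lower_bound = -1000, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("EX_o2", c(o2_e = -1), lower_bound = -1000, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("TR_A", c(A_e = -1, A_c = 1)),
      reaction("TR_o2", c(o2_e = -1, o2_c = 1)),
      reaction("OXID", c(A_c = -1, o2_c = -1, P_c = 1)),
      reaction("biomass", c(P_c = -1), is_biomass = TRUE)),
    biomass_reaction_id = "biomass")
}

## random small valid model with at most `max_rxns` reactions; used for the
## LP-vs-vertex-enumeration comparison
random_lp_model <- function(seed, max_rxns = 8) {
  set.seed(seed)
  n_ext <- sample(1:2, 1)
  ext <- sprintf("X%d_e", seq_len(n_ext))
  n_int <- sample(1:3, 1)
  int <- sprintf("M%d_c", seq_len(n_int))
  mets <- c(lapply(ext, metabolite, compartment = "extracellular"),
            lapply(int, metabolite))
  rxns <- list()
  for (i in seq_len(n_ext)) {
    rxns <- c(rxns, list(
      reaction(sprintf("EX_%d", i), stats::setNames(-1, ext[i]),
               lower_bound = -1000, upper_bound = 1000, is_exchange = TRUE),
      reaction(sprintf("TR_%d", i),
               stats::setNames(c(-1, 1), c(ext[i], int[sample(n_int, 1)])),
               upper_bound = sample(c(5, 10, 20), 1))))
  }
  budget <- max_rxns - length(rxns) - 1L
  n_extra <- sample(0:max(budget, 0), 1)
  for (j in seq_len(n_extra)) {
    from <- sample(n_int, 1); to <- sample(n_int, 1)
    if (from == to) next
    rev <- runif(1) < 0.3
    rxns <- c(rxns, list(
      reaction(sprintf("R_%d", j),
               stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                               c(int[from], int[to])),
               lower_bound = if (rev) -sample(c(5, 10), 1) else 0,
               upper_bound = sample(c(5, 10, 20), 1))))
  }
  k <- sample(seq_len(n_int), 1)
  rxns <- c(rxns, list(
    reaction("biomass", stats::setNames(rep(-1, k), int[seq_len(k)]),
             is_biomass = TRUE)))
  metabolic_model(sprintf("rand_%03d", seed), mets, rxns, "biomass")
}

## ---- LP oracle: exhaustive vertex enumeration -------------------------

## Maximum of obj over {v : S v = 0, lb <= v <= ub} by enumerating basic
## solutions: every vertex has n - rank(S) variables at a bound.
vertex_enum_optimum <- function(S, lb, ub, obj, tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  qr_t <- qr(t(S))
  r <- qr_t$rank
  Sr <- S[qr_t$pivot[seq_len(r)], , drop = FALSE]   # independent rows
  best <- -Inf
  if (r == 0L) {
    v <- ifelse(obj > 0, ub, lb)
    return(sum(obj * v))
  }
  basics <- utils::combn(n, r, simplify = FALSE)
  for (B in basics) {
    N <- setdiff(seq_len(n), B)
    SB <- Sr[, B, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    n_free <- length(N)
    for (mask in 0:(2^n_free - 1)) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(n_free) - 1)))
      vN <- ifelse(at_ub, ub[N], lb[N])
      vB <- tryCatch(solve(SB, -Sr[, N, drop = FALSE] %*% vN),
                     error = function(e) NULL)
      if (is.null(vB)) next
      if (any(vB < lb[B] - 1e-7) || any(vB > ub[B] + 1e-7)) next
      v <- numeric(n); v[N] <- vN; v[B] <- vB
      best <- max(best, sum(obj * v))
    }
  }
  best
}

## oracle optimum of the growth LP of a model under a medium
fba_vertex_optimum <- function(model, med) {
  S <- s_matrix(model)
  bounds <- microrep:::apply_medium(model, med)
  obj <- as.numeric(colnames(S) == model$biomass_reaction_id)
  vertex_enum_optimum(S, bounds$lb, bounds$ub, obj)
}

## ---- distance oracles -------------------------------------------------

brute_jaccard <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(M[i, ] == 1); b <- which(M[j, ] == 1)
    un <- length(union(a, b))
    D[i, j] <- if (un == 0) 0 else 1 - length(intersect(a, b)) / un
  }
  D
}

## patristic distances by explicit root-path enumeration
brute_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  len_of <- numeric(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  path_to_root <- function(i) {
    nodes <- i; lens <- 0
    while (i != root) {
      lens <- c(lens, lens[length(lens)] + len_of[i])
      i <- parent_of[i]
      nodes <- c(nodes, i)
    }
    stats::setNames(lens, nodes)
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    ## the most recent common ancestor is the shallowest shared node along
    ## the root paths (smallest accumulated length from the leaf)
    mrca <- common[which.min(paths[[i]][common])]
    D[i, j] <- paths[[i]][[mrca]] + paths[[j]][[mrca]]
  }
  D
}

## ---- clustering oracle ------------------------------------------------

## naive O(n^3) complete-linkage agglomeration; returns merge heights and a
## labeling function for any k
brute_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list(lapply(clusters, identity))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights,
       partition_at = function(k) partitions[[n - k + 1L]])
}

## canonical form of a partition (list of index vectors) for comparison
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

## cluster_assignment labels -> partition over organism indices in `orgs`
labels_to_partition <- function(labels, orgs) {
  canonical_partition(unname(lapply(split(match(names(labels), orgs),
                                          labels), as.integer)))
}

## random continuous dissimilarity matrix (ties have probability zero, so
## the complete-linkage merge sequence is unambiguous)
random_continuous_dist <- function(seed, n) {
  set.seed(seed)
  X <- matrix(rnorm(n * 4), n, 4)
  D <- as.matrix(dist(X))
  D <- D / max(D)
  dimnames(D) <- list(sprintf("o%02d", seq_len(n)), sprintf("o%02d", seq_len(n)))
  org_dist(D, "metabolic")
}

## ---- misc -------------------------------------------------------------

make_pairs <- function(x, y = NULL, z = NULL) {
  df <- data.frame(org_i = sprintf("a%04d", seq_along(x)),
                   org_j = sprintf("b%04d", seq_along(x)), x = x)
  if (!is.null(y)) df$y <- y
  if (!is.null(z)) df$z <- z
  class(df) <- c("paired_distances", "data.frame")
  df
}

random_binary_profile <- function(seed, n_org = 8, n_feat = 20) {
  set.seed(seed)
  M <- matrix(rbinom(n_org * n_feat, 1, 0.5), n_org, n_feat,
              dimnames = list(sprintf("o%02d", seq_len(n_org)),
                              sprintf("f%02d", seq_len(n_feat))))
  binary_profile(M, "reaction")
}

## Procrustes residual (translation + rotation/reflection + scale)
procrustes_ss <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(Y^2)
  sum((X - sc * Y %*% t(R))^2)
}

## the default synthetic community, generated once per test run
community_cache <- new.env(parent = emptyenv())
default_community <- function() {
  if (is.null(community_cache$default))
    community_cache$default <- simulate_community(sim_config())
  community_cache$default
}
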