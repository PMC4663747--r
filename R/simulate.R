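## Synthetic community generator with construction-time ground truth.
##
## The generator emulates the statistical structure the downstream analyses
## assume, at a scale where everything can be verified exactly:
##
##   * a pure-birth (Yule) tree over the organisms (branch lengths in units
##     of expected gain/loss events per feature);
##   * reaction repertoires evolved along the tree by an independent
##     two-state (gain/loss) Markov chain per feature, which induces the
##     saturating, exponential-like relation between phylogenetic and
##     repertoire distance;
##   * small FBA-ready models wired from pathway templates so that nutrient
##     essentiality is decided structurally -- nutrient k is essential for
##     an organism exactly when that organism lacks the alternative route
##     feeding precursor k from the neighboring nutrient -- giving ground
##     truth that is exact by construction, never tuned numerically;
##   * clade-derived taxonomy labels at two nested ranks obtained by
##     cutting the tree at two depths.
##
## The whole community is a pure function of its configuration (seed
## included). Horizontal transfer is deliberately not modeled: features
## evolve independently along the tree.

#' Simulation configuration
#'
#' @param n_organisms number of tips / models.
#' @param birth_rate Yule speciation rate per unit branch length. The
#'   default 5 puts the expected root-to-tip depth of a 100-tip tree near
#'   0.84, i.e. roughly 1.7 expected gain/loss events per feature along a
#'   typical tip-to-tip path at `gain_rate = loss_rate = 1` -- a mix of
#'   unsaturated and saturating pairs.
#' @param n_features number of evolving repertoire features.
#' @param gain_rate,loss_rate per-feature 0->1 / 1->0 rates per unit branch
#'   length.
#' @param n_nutrients number of external nutrients per model (>= 2).
#' @param p_alternative_route probability that a present alternative-route
#'   feature is actually wired into the model. At the default 1 the
#'   essentiality phenotype is fully encoded by the repertoire.
#' @param noise_sd log10-scale noise used by direct regression fixtures.
#' @param n_class,n_genus number of clades at the coarse and fine taxonomy
#'   rank (`n_class <= n_genus <= n_organisms`); the defaults cap the usual
#'   5 classes / 15 genera at the community size.
#' @param seed RNG seed; the generated community is a pure function of this
#'   configuration.
#' @export
sim_config <- function(n_organisms = 100, birth_rate = 5, n_features = 300,
                       gain_rate = 1, loss_rate = 1, n_nutrients = 15,
                       p_alternative_route = 1, noise_sd = 0.1,
                       n_class = NULL, n_genus = NULL, seed = 42) {
  if (is.null(n_class)) n_class <- min(5L, n_organisms)
  if (is.null(n_genus)) n_genus <- min(15L, n_organisms)
  stopifnot(is_count(n_organisms, 2), is_count(n_features, 2),
            is_count(n_nutrients, 2),
            is_number(birth_rate), birth_rate > 0,
            is_number(gain_rate), gain_rate > 0,
            is_number(loss_rate), loss_rate > 0,
            is_number(p_alternative_route),
            p_alternative_route >= 0, p_alternative_route <= 1,
            is_number(noise_sd), noise_sd >= 0,
            is_count(n_class, 1), is_count(n_genus, 1),
            n_class <= n_genus, n_genus <= n_organisms,
            is_count(seed, 0), seed < 2^31 - 10)
  if (n_nutrients > n_features)
    stop_validation("sim_config: n_nutrients cannot exceed n_features")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Starts from a root bifurcation; while k lineages are alive the next
#' split waits an Exp(k * birth_rate) time and hits a uniformly chosen
#' lineage. After the n-th lineage appears one further Exp(n * birth_rate)
#' epoch elapses, and all tips extend to the present, so the tree is
#' ultrametric with expected depth `sum(1 / (birth_rate * (2:n)))`.
#'
#' @param config a [sim_config()].
#' @return an `ape::phylo` tree with tips `org_0001`, `org_0002`, ...
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_organisms; b <- config$birth_rate
  with_local_seed(config$seed, {
    ## nodes are grown as a table: start time, split time (NA for tips),
    ## children indices (0 = none yet)
    start <- c(0, 0); split <- c(NA_real_, NA_real_)
    child1 <- c(0L, 0L); child2 <- c(0L, 0L)
    active <- c(1L, 2L)
    t_now <- 0
    while (length(active) < n) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = k * b)
      i <- active[sample.int(k, 1)]
      c1 <- length(start) + 1L; c2 <- length(start) + 2L
      start <- c(start, t_now, t_now)
      split <- c(split, NA_real_, NA_real_)
      child1 <- c(child1, 0L, 0L); child2 <- c(child2, 0L, 0L)
      child1[i] <- c1; child2[i] <- c2
      split[i] <- t_now
      active <- c(setdiff(active, i), c1, c2)
    }
    t_end <- t_now + stats::rexp(1, rate = n * b)
    tip_counter <- 0L
    to_newick <- function(i) {
      end_i <- if (is.na(split[i])) t_end else split[i]
      len <- end_i - start[i]
      if (child1[i] == 0L) {
        tip_counter <<- tip_counter + 1L
        sprintf("org_%04d:%.15g", tip_counter, len)
      } else {
        sprintf("(%s,%s):%.15g", to_newick(child1[i]), to_newick(child2[i]), len)
      }
    }
    nwk <- sprintf("(%s,%s);", to_newick(1L), to_newick(2L))
    tree <- ape::read.tree(text = nwk)
    validate_tree(tree)
    tree
  })
}

#' Evolve binary repertoire features along a tree
#'
#' Each feature evolves independently as a two-state Markov chain with gain
#' rate lambda and loss rate mu: over a branch of length t,
#' `P(0 -> 1) = pi1 (1 - exp(-(lambda + mu) t))` and
#' `P(1 -> 0) = pi0 (1 - exp(-(lambda + mu) t))` with stationary presence
#' `pi1 = lambda / (lambda + mu)`; the root state is drawn from the
#' stationary distribution.
#'
#' @param tree a rooted `phylo`.
#' @param config a [sim_config()].
#' @return a [binary_profile()] of tips by features (`feat_0001`, ...).
#' @export
evolve_profiles <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_tree(tree)
  lam <- config$gain_rate; mu <- config$loss_rate
  rate <- lam + mu
  pi1 <- lam / rate
  nf <- config$n_features
  ntip <- length(tree$tip.label)
  with_local_seed(config$seed + 1L, {
    states <- matrix(NA_integer_, ntip + tree$Nnode, nf)
    root <- ntip + 1L
    states[root, ] <- stats::rbinom(nf, 1, pi1)
    for (e in rev(ape::postorder(tree))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      p_gain <- pi1 * (1 - exp(-rate * t_len))
      p_loss <- (1 - pi1) * (1 - exp(-rate * t_len))
      s <- states[par, ]
      gain <- stats::rbinom(nf, 1, p_gain)
      loss <- stats::rbinom(nf, 1, p_loss)
      states[child, ] <- ifelse(s == 0L, gain, 1L - loss)
    }
    M <- states[seq_len(ntip), , drop = FALSE]
    dimnames(M) <- list(tree$tip.label,
                        sprintf("feat_%04d", seq_len(nf)))
    M <- M[sort(rownames(M)), , drop = FALSE]
    binary_profile(M, "reaction")
  })
}

nutrient_met <- function(k, where) sprintf("nut%02d_%s", k, where)
precursor_met <- function(k) sprintf("pre%02d_c", k)

#' Assemble FBA-ready models from evolved repertoires
#'
#' Every organism receives, per nutrient k: an exchange and a transport
#' reaction, a core pathway `nut_k -> pre_k`, and -- when the k-th evolved
#' feature (the "alternative route" controller) is present and a
#' Bernoulli(`p_alternative_route`) coin allows it -- an alternative
#' pathway feeding `pre_k` from the neighboring nutrient k'. A single
#' biomass reaction consumes all precursors. Every other present feature
#' becomes an inert (flux-silent, dead-end) reaction so that the model's
#' reaction repertoire mirrors the evolved profile. No reaction touches
#' oxygen, so every model grows anaerobically by construction.
#'
#' Nutrient k is essential exactly when the alternative route for
#' precursor k was not wired in; this ground truth is recorded from the
#' wiring, without running FBA.
#'
#' @param profiles a [binary_profile()] from [evolve_profiles()].
#' @param config a [sim_config()].
#' @return list with `collection` (a [model_collection()]) and
#'   `truth_essential` (named list: organism -> essential external
#'   nutrient metabolite ids).
#' @export
assemble_models <- function(profiles, config) {
  stopifnot(inherits(profiles, "binary_profile"), inherits(config, "sim_config"))
  K <- config$n_nutrients
  if (K > ncol(profiles$values))
    stop_runtime("assemble_models: %d nutrients need at least %d profile features",
                 K, K)
  feats <- colnames(profiles$values)
  controllers <- feats[seq_len(K)]
  orgs <- rownames(profiles$values)
  with_local_seed(config$seed + 2L, {
    models <- vector("list", length(orgs))
    truth <- stats::setNames(vector("list", length(orgs)), orgs)
    for (oi in seq_along(orgs)) {
      o <- orgs[oi]
      present <- feats[profiles$values[o, ] == 1L]
      alt <- logical(K)
      for (k in seq_len(K)) {
        alt[k] <- controllers[k] %in% present &&
          (config$p_alternative_route >= 1 ||
             stats::runif(1) < config$p_alternative_route)
      }
      mets <- list()
      rxns <- list()
      for (k in seq_len(K)) {
        ne <- nutrient_met(k, "e"); nc <- nutrient_met(k, "c"); pc <- precursor_met(k)
        mets <- c(mets, list(metabolite(ne, compartment = "extracellular"),
                             metabolite(nc), metabolite(pc)))
        rxns <- c(rxns, list(
          reaction(sprintf("EX_nut%02d", k), stats::setNames(-1, ne),
                   lower_bound = -DEFAULT_UB, upper_bound = DEFAULT_UB,
                   is_exchange = TRUE),
          reaction(sprintf("TR_nut%02d", k),
                   stats::setNames(c(-1, 1), c(ne, nc))),
          reaction(sprintf("CORE_nut%02d", k),
                   stats::setNames(c(-1, 1), c(nc, pc)))))
      }
      for (k in which(alt)) {
        kp <- k %% K + 1L   # neighboring nutrient feeds precursor k
        rxns <- c(rxns, list(
          reaction(sprintf("ALT_%s", controllers[k]),
                   stats::setNames(c(-1, 1),
                                   c(nutrient_met(kp, "c"), precursor_met(k))))))
      }
      for (f in setdiff(present, controllers)) {
        ma <- sprintf("m_%s_a", f); mb <- sprintf("m_%s_b", f)
        mets <- c(mets, list(metabolite(ma), metabolite(mb)))
        rxns <- c(rxns, list(
          reaction(sprintf("RXN_%s", f), stats::setNames(c(-1, 1), c(ma, mb)))))
      }
      rxns <- c(rxns, list(
        reaction("biomass",
                 stats::setNames(rep(-1, K), vapply(seq_len(K), precursor_met,
                                                    character(1))),
                 is_biomass = TRUE)))
      m <- metabolic_model(o, mets, rxns, "biomass")
      viol <- validate_model(m)
      if (length(viol))
        stop_runtime("assemble_models produced an invalid model for '%s': %s",
                     o, paste(viol, collapse = "; "))
      models[[oi]] <- m
      truth[[o]] <- vapply(which(!alt), nutrient_met, character(1), where = "e")
    }
    list(collection = model_collection(models), truth_essential = truth)
  })
}

#' Clade taxonomy labels at two nested ranks
#'
#' Cuts the tree at the two depths yielding exactly `n_class` and `n_genus`
#' monophyletic clades; every leaf receives both labels and genus clades
#' nest within class clades by construction. Counts unreachable on the
#' given topology (tied node depths, polytomies) raise a labeling error.
#'
#' @param tree a rooted binary `phylo` with branch lengths.
#' @param n_class,n_genus requested clade counts, `n_class <= n_genus <=`
#'   number of leaves.
#' @return data.frame with columns `organism`, `class`, `genus`.
#' @export
label_taxa <- function(tree, n_class, n_genus) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  stopifnot(is_count(n_class, 1), is_count(n_genus, 1))
  if (!(n_class <= n_genus && n_genus <= ntip))
    stop_validation("label_taxa: need 1 <= n_class <= n_genus <= %d", ntip)

  depth <- ape::node.depth.edgelength(tree)
  root <- ntip + 1L
  internal <- setdiff(seq_len(ntip + tree$Nnode), c(seq_len(ntip), root))
  d_int <- sort(depth[internal])
  min_tip <- min(depth[seq_len(ntip)])

  cut_labels <- function(g, prefix) {
    if (g == 1L)
      return(stats::setNames(rep(sprintf("%s01", prefix), ntip), tree$tip.label))
    breaks <- c(0, d_int, min_tip)   # lineage count is 2 + #{internal <= h}
    lo <- breaks[g - 1L]; hi <- breaks[g]
    if (!(lo < hi))
      stop_runtime("label_taxa: %d clades unreachable on this topology (tied depths)", g)
    h <- (lo + hi) / 2
    cross <- which(depth[tree$edge[, 1]] <= h & depth[tree$edge[, 2]] > h)
    if (length(cross) != g)
      stop_runtime("label_taxa: %d clades unreachable on this topology", g)
    lab <- stats::setNames(rep(NA_character_, ntip), tree$tip.label)
    clades <- lapply(tree$edge[cross, 2], function(node) tips_below(tree, node))
    clades <- clades[order(vapply(clades, min, character(1)))]
    for (ci in seq_along(clades))
      lab[clades[[ci]]] <- sprintf("%s%02d", prefix, ci)
    if (anyNA(lab))
      stop_runtime("label_taxa: some leaves terminate above the cut depth")
    lab
  }
  cls <- cut_labels(n_class, "cls")
  gen <- cut_labels(n_genus, "gen")
  out <- data.frame(organism = tree$tip.label, class = unname(cls),
                    genus = unname(gen), stringsAsFactors = FALSE)
  out <- out[order(out$organism), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## tip labels descending from a node (the node itself when it is a tip)
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- character()
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, tree$tip.label[ch[ch <= ntip]])
    todo <- c(todo, ch[ch > ntip])
  }
  sort(tips)
}

#' Generate a full synthetic community
#'
#' Runs [simulate_tree()], [evolve_profiles()], [assemble_models()] and
#' [label_taxa()], attaches the clade taxonomy to every model, and returns
#' everything together with the construction ground truth.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_community`: `tree`, `models`
#'   (a [model_collection()]), `truth_essential`, `taxonomy` (data.frame),
#'   `profiles` (the evolved repertoire), and the `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config)
  profiles <- evolve_profiles(tree, config)
  am <- assemble_models(profiles, config)
  taxonomy <- label_taxa(tree, config$n_class, config$n_genus)
  rownames(taxonomy) <- taxonomy$organism
  models <- lapply(am$collection$models, function(m) {
    m$taxonomy <- list(class = taxonomy[m$organism_id, "class"],
                       genus = taxonomy[m$organism_id, "genus"])
    m
  })
  rownames(taxonomy) <- NULL
  structure(list(tree = tree,
                 models = model_collection(models),
                 truth_essential = am$truth_essential,
                 taxonomy = taxonomy,
                 profiles = profiles,
                 config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d organisms, %d features, %d nutrients, seed %d\n",
              x$config$n_organisms, x$config$n_features, x$config$n_nutrients,
              x$config$seed))
  invisible(x)
}

#' Ground-truth essential-nutrient profile matrix
#'
#' @param community a `synthetic_community`.
#' @return a [binary_profile()] of organisms by external nutrient ids with
#'   `feature_kind = "essential_nutrient"`.
#' @export
truth_essential_profile <- function(community) {
  stopifnot(inherits(community, "synthetic_community"))
  orgs <- organism_ids(community$models)
  nuts <- sort(vapply(seq_len(community$config$n_nutrients), nutrient_met,
                      character(1), where = "e"))
  M <- matrix(0L, length(orgs), length(nuts), dimnames = list(orgs, nuts))
  for (o in orgs) M[o, community$truth_essential[[o]]] <- 1L
  binary_profile(M, "essential_nutrient")
}
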