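## Cross-distance regressions: the genotype-phenotype-phylogeny core.
##
## Pairwise distances over one aligned organism set are assembled into a
## pair table (one row per unordered pair) and modeled as
##
##     y = 10^(alpha + beta * x)   (phylogenetic distance y on metabolic x;
##                                  fitted as OLS of log10 y on x, i.e. a
##                                  linear regression of semi-log data)
##     z = alpha + beta * x        (essential-nutrient distance z on x)
##
## The exponential fit is accompanied by the Spearman rank correlation of
## (x, y), the linear fit by the Pearson correlation of (x, z). R^2 and
## RMSE for the exponential model are reported on the log10 scale by
## default (matching the semi-log regression), with `rmse_scale =
## "original"` available to report back-transformed residuals.

#' Pair table of distances over one organism set
#'
#' @param metabolic,phylogenetic,nutrient [org_dist()] objects on the same
#'   canonical organism order (`nutrient` optional). Use
#'   [align_organisms()] first when sets differ.
#' @return a `paired_distances` data.frame with one row per unordered pair
#'   (`org_i < org_j`): columns `org_i`, `org_j`, `x` (metabolic), `y`
#'   (phylogenetic), and `z` (nutrient, when given); `N(N-1)/2` rows.
#' @export
pair_table <- function(metabolic, phylogenetic = NULL, nutrient = NULL) {
  stopifnot(inherits(metabolic, "org_dist"))
  orgs <- organism_ids(metabolic)
  if (length(orgs) < 2L) stop_validation("pair_table needs at least 2 organisms")
  for (other in list(phylogenetic, nutrient)) {
    if (!is.null(other) && !identical(organism_ids(other), orgs))
      stop_validation("pair_table: input matrices are not aligned on the same organisms")
  }
  idx <- which(upper.tri(metabolic$values), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(org_i = orgs[idx[, 1]], org_j = orgs[idx[, 2]],
                    x = metabolic$values[idx], stringsAsFactors = FALSE)
  if (!is.null(phylogenetic)) out$y <- phylogenetic$values[idx]
  if (!is.null(nutrient)) out$z <- nutrient$values[idx]
  class(out) <- c("paired_distances", "data.frame")
  attr(out, "n_organisms") <- length(orgs)
  attr(out, "subset_label") <- "All taxa"
  out
}

## correlation with the convention that zero-variance input gives 0
## (a constant response carries no association)
cor_or_zero <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y, method = method)
}

new_fit <- function(model_kind, alpha, beta, correlation_kind, correlation,
                    r_squared, rmse, n_used, n_pairs, subset_label) {
  structure(list(model_kind = model_kind, alpha = alpha, beta = beta,
                 correlation_kind = correlation_kind, correlation = correlation,
                 r_squared = r_squared, rmse = rmse,
                 n_used = n_used, n_pairs = n_pairs,
                 subset_label = subset_label),
            class = "repertoire_fit")
}

#' @export
print.repertoire_fit <- function(x, ...) {
  cat(sprintf("<repertoire_fit> %s [%s]: alpha = %.4g, beta = %.4g, %s = %.3f, R2 = %.3f, RMSE = %.3g (n = %d/%d)\n",
              x$model_kind, x$subset_label, x$alpha, x$beta,
              x$correlation_kind, x$correlation, x$r_squared, x$rmse,
              x$n_used, x$n_pairs))
  invisible(x)
}

#' Exponential model of phylogenetic on metabolic distance
#'
#' Fits `y = 10^(alpha + beta x)` by ordinary least squares of `log10(y)`
#' on `x` over the pairs with `y > 0` (identical leaves are excluded from
#' the log fit and reported through `n_used`). The Spearman correlation is
#' computed over all pairs.
#'
#' @param pairs a [pair_table()] with a `y` column.
#' @param rmse_scale report RMSE (and R^2 residuals) on the `"log"` scale
#'   of the semi-log regression or on the `"original"` response scale.
#' @return a `repertoire_fit`.
#' @export
fit_exponential <- function(pairs, rmse_scale = c("log", "original")) {
  rmse_scale <- match.arg(rmse_scale)
  if (is.null(pairs$y)) stop_validation("fit_exponential: pair table has no y column")
  keep <- pairs$y > 0
  n_used <- sum(keep)
  if (n_used < 3L)
    stop_runtime("fit_exponential: need at least 3 pairs with y > 0 (got %d)", n_used)
  x <- pairs$x[keep]; ly <- log10(pairs$y[keep])
  if (stats::sd(x) == 0)
    stop_runtime("fit_exponential: zero variance in metabolic distance")
  fit <- stats::lm(ly ~ x)
  res <- if (rmse_scale == "log") stats::residuals(fit)
         else pairs$y[keep] - 10^stats::fitted(fit)
  new_fit("exponential",
          alpha = unname(stats::coef(fit)[1]),
          beta = unname(stats::coef(fit)[2]),
          correlation_kind = "spearman",
          correlation = cor_or_zero(pairs$x, pairs$y, "spearman"),
          r_squared = suppressWarnings(summary(fit)$r.squared),
          rmse = sqrt(mean(res^2)),
          n_used = n_used, n_pairs = nrow(pairs),
          subset_label = attr(pairs, "subset_label") %||% "All taxa")
}

#' Linear model of essential-nutrient on metabolic distance
#'
#' Fits `z = alpha + beta x` by ordinary least squares with the Pearson
#' correlation as the association measure; R^2 and RMSE are on the z scale.
#'
#' @param pairs a [pair_table()] with a `z` column.
#' @return a `repertoire_fit`.
#' @export
fit_linear <- function(pairs) {
  if (is.null(pairs$z)) stop_validation("fit_linear: pair table has no z column")
  if (nrow(pairs) < 3L)
    stop_runtime("fit_linear: need at least 3 pairs (got %d)", nrow(pairs))
  if (stats::sd(pairs$x) == 0)
    stop_runtime("fit_linear: zero variance in metabolic distance")
  fit <- stats::lm(z ~ x, data = pairs)
  new_fit("linear",
          alpha = unname(stats::coef(fit)[1]),
          beta = unname(stats::coef(fit)[2]),
          correlation_kind = "pearson",
          correlation = cor_or_zero(pairs$x, pairs$z, "pearson"),
          r_squared = suppressWarnings(summary(fit)$r.squared),
          rmse = sqrt(mean(stats::residuals(fit)^2)),
          n_used = nrow(pairs), n_pairs = nrow(pairs),
          subset_label = attr(pairs, "subset_label") %||% "All taxa")
}

#' Restrict a pair table to one taxon
#'
#' @param taxonomy data.frame with columns `organism` plus rank columns
#'   (`class`, `genus`, ...), or a [model_collection()] whose models carry
#'   taxonomy.
#' @param pairs a [pair_table()].
#' @param rank taxonomy column to match (e.g. `"class"` or `"genus"`).
#' @param label taxon label; at least 3 member organisms are required.
#' @return the pair table restricted to within-taxon pairs.
#' @export
taxon_subset <- function(taxonomy, pairs, rank, label) {
  tax <- as_taxonomy(taxonomy)
  if (!rank %in% colnames(tax))
    stop_validation("taxon_subset: unknown rank '%s'", rank)
  members <- tax$organism[!is.na(tax[[rank]]) & tax[[rank]] == label]
  if (length(members) < 3L)
    stop_runtime("taxon_subset: %s '%s' has %d member(s); at least 3 required",
                 rank, label, length(members))
  keep <- pairs$org_i %in% members & pairs$org_j %in% members
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_distances", "data.frame")
  attr(out, "n_organisms") <- length(members)
  attr(out, "subset_label") <- paste0(rank, ":", label)
  out
}

#' Coerce taxonomy input to a data.frame
#' @noRd
as_taxonomy <- function(taxonomy) {
  if (inherits(taxonomy, "model_collection")) {
    ranks <- unique(unlist(lapply(taxonomy$models, function(m) names(m$taxonomy))))
    df <- data.frame(organism = organism_ids(taxonomy), stringsAsFactors = FALSE)
    for (r in ranks)
      df[[r]] <- vapply(taxonomy$models, function(m)
        m$taxonomy[[r]] %||% NA_character_, character(1))
    rownames(df) <- NULL
    return(df)
  }
  stopifnot(is.data.frame(taxonomy), "organism" %in% colnames(taxonomy))
  taxonomy
}

#' Fit-summary table across taxon subsets
#'
#' One row per subset (plus "All taxa") with the exponential model's
#' Spearman correlation, R^2 and RMSE and the linear model's Pearson
#' correlation, R^2 and RMSE. Association and R^2 values above 0.5 are
#' flagged in the `flagged` column; a degenerate subset yields a row whose
#' `note` carries the error instead of aborting the table.
#'
#' @param taxonomy see [taxon_subset()].
#' @param pairs the full [pair_table()] (needs `y` and `z` columns).
#' @param subsets list of `c(rank, label)` pairs or `"rank:label"` strings.
#' @param rmse_scale passed to [fit_exponential()].
#' @return data.frame, one row per subset.
#' @export
fit_summary_table <- function(taxonomy, pairs, subsets = list(),
                              rmse_scale = "log") {
  parse_subset <- function(s) {
    if (is.character(s) && length(s) == 1L) strsplit(s, ":", fixed = TRUE)[[1]]
    else s
  }
  entries <- c(list(NULL), lapply(subsets, parse_subset))
  rows <- lapply(entries, function(e) {
    label <- if (is.null(e)) "All taxa" else paste0(e[1], ":", e[2])
    row <- data.frame(subset = label, n_organisms = NA_integer_,
                      n_pairs = NA_integer_,
                      spearman = NA_real_, r2_exp = NA_real_, rmse_exp = NA_real_,
                      pearson = NA_real_, r2_lin = NA_real_, rmse_lin = NA_real_,
                      flagged = "", note = "", stringsAsFactors = FALSE)
    tryCatch({
      sub <- if (is.null(e)) pairs else taxon_subset(taxonomy, pairs, e[1], e[2])
      fe <- fit_exponential(sub, rmse_scale = rmse_scale)
      fl <- fit_linear(sub)
      row$n_organisms <- attr(sub, "n_organisms")
      row$n_pairs <- nrow(sub)
      row$spearman <- fe$correlation; row$r2_exp <- fe$r_squared
      row$rmse_exp <- fe$rmse
      row$pearson <- fl$correlation; row$r2_lin <- fl$r_squared
      row$rmse_lin <- fl$rmse
      hi <- c(spearman = fe$correlation, r2_exp = fe$r_squared,
              pearson = fl$correlation, r2_lin = fl$r_squared) > 0.5
      row$flagged <- paste(names(hi)[hi], collapse = ",")
      row
    }, error = function(err) {
      row$note <- conditionMessage(err)
      row
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Moving average of a response over pairs sorted by metabolic distance
#'
#' Sliding mean with a window of `ceiling(window_fraction * n)` pairs and
#' step 1; each output point carries the window's mean x as its center.
#' Diagnostic only (the blue trend curve), not part of any fit.
#'
#' @param pairs a [pair_table()].
#' @param response `"y"` or `"z"`.
#' @param window_fraction window size as a fraction of the pair count.
#' @return data.frame with `x_center` and `mean_response`.
#' @export
moving_average <- function(pairs, response = c("y", "z"),
                           window_fraction = 0.05) {
  response <- match.arg(response)
  if (is.null(pairs[[response]]))
    stop_validation("moving_average: pair table has no %s column", response)
  n <- nrow(pairs)
  if (n == 0L) stop_validation("moving_average: empty pair table")
  stopifnot(is_number(window_fraction), window_fraction > 0, window_fraction <= 1)
  w <- ceiling(window_fraction * n)
  ord <- order(pairs$x)
  x <- pairs$x[ord]; r <- pairs[[response]][ord]
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  }
  out <- data.frame(x_center = roll(x), mean_response = roll(r))
  attr(out, "window_fraction") <- window_fraction
  attr(out, "window_size") <- w
  out
}
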