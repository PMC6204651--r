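#' Effective species richness per increment with resampling CIs
#'
#' Computes, per depth increment, the total count, raw species richness,
#' Shannon entropy H (natural log) and the effective species richness
#' exp(H), plus a subsampling mean and 95% confidence interval: each
#' increment is subsampled without replacement to the common minimum N of
#' the included increments (rarefaction-style), `iterations` times, and the
#' mean and 2.5%/97.5% quantiles of the resampled exp(H) are reported.
#' Fractional counts (plate-derived) are handled by weighted sampling
#' without replacement. Empty increments are skipped with a log entry in
#' the `skipped` attribute.
#'
#' @param x a [CoreAssemblage-class] or an increments-by-taxa matrix.
#' @param iterations number of resampling iterations (default 1000).
#' @param seed RNG seed.
#' @param minN subsample size; defaults to the smallest increment total
#'   (floored) across non-empty increments.
#' @return data.frame with columns `increment`, `n`, `richness_raw`,
#'   `shannon_h`, `effective_richness`, `mean_resampled`, `ci_lo`, `ci_hi`.
#' @examples
#' m <- rbind(a = c(sp1 = 25, sp2 = 25, sp3 = 25, sp4 = 25))
#' incrementDiversity(m, iterations = 100)$effective_richness  # 4
#' @export
incrementDiversity <- function(x, iterations = 1000L, seed = 1L, minN = NULL) {
  mat <- if (is(x, "CoreAssemblage")) abundanceMatrix(x) else as.matrix(x)
  tot <- rowSums(mat)
  skipped <- rownames(mat)[tot == 0]
  mat <- mat[tot > 0, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no non-empty increments")
  tot <- rowSums(mat)
  if (is.null(minN)) minN <- floor(min(tot))
  if (minN < 1) stop("subsample size must be at least 1")
  H <- vegan::diversity(mat, index = "shannon")
  out <- data.frame(
    increment = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    n = tot,
    richness_raw = rowSums(mat > 0),
    shannon_h = as.numeric(H),
    effective_richness = exp(as.numeric(H)),
    row.names = NULL
  )
  res <- withr_seed(seed, {
    lapply(seq_len(nrow(mat)), function(i) {
      vapply(seq_len(iterations), function(j) {
        sub <- .subsampleCounts(mat[i, ], minN)
        exp(vegan::diversity(sub, index = "shannon"))
      }, numeric(1))
    })
  })
  out$mean_resampled <- vapply(res, mean, numeric(1))
  out$ci_lo <- vapply(res, quantile, numeric(1), probs = 0.025, names = FALSE)
  out$ci_hi <- vapply(res, quantile, numeric(1), probs = 0.975, names = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "minN") <- minN
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw `size` individuals without replacement from a count vector; supports
# fractional counts by treating the fractional remainder of each taxon as a
# partial individual with proportional selection weight.
.subsampleCounts <- function(counts, size) {
  counts <- counts[counts > 0]
  fl <- floor(counts)
  frac <- counts - fl
  taxon <- c(rep(seq_along(counts), fl), which(frac > 1e-12))
  w <- c(rep(1, sum(fl)), frac[frac > 1e-12])
  if (size > length(taxon)) size <- length(taxon)
  pick <- if (all(w == 1)) sample(seq_along(taxon), size)
          else sample(seq_along(taxon), size, prob = w)
  tab <- tabulate(taxon[pick], nbins = length(counts))
  tab
}

#' Wilcoxon rank contrasts of effective richness between units
#'
#' Two-sided Wilcoxon rank-sum tests on per-increment effective species
#' richness between unit pairs (by default every consecutive pair in the
#' order given).
#'
#' @param values numeric vector of per-increment exp(H).
#' @param units vector of unit labels aligned with `values`.
#' @param comparisons optional 2-column matrix/data.frame of unit pairs;
#'   default: consecutive units in their sorted order.
#' @return data.frame with `unit_a`, `unit_b`, `n_a`, `n_b`, `statistic`,
#'   `p_value`.
#' @export
diversityContrast <- function(values, units, comparisons = NULL) {
  stopifnot(length(values) == length(units))
  lev <- sort(unique(units))
  if (is.null(comparisons)) {
    if (length(lev) < 2L) stop("need at least two units to contrast")
    comparisons <- cbind(lev[-length(lev)], lev[-1])
  }
  comparisons <- as.matrix(comparisons)
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    a <- values[units == comparisons[i, 1]]
    b <- values[units == comparisons[i, 2]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = NULL))
    data.frame(unit_a = comparisons[i, 1], unit_b = comparisons[i, 2],
               n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis distances on square-root transformed relative abundances
#'
#' The standard transformation chain for death-assemblage composition:
#' counts are converted to relative abundances per increment, square-root
#' transformed, and Bray-Curtis dissimilarities computed.
#'
#' @param x a `CoreAssemblage` or increments-by-taxa matrix.
#' @param transform `"sqrt_rel"` (default), `"rel"`, or `"none"`.
#' @return a `dist` object (values in `[0, 1]`, zero diagonal).
#' @export
brayCurtisDist <- function(x, transform = c("sqrt_rel", "rel", "none")) {
  transform <- match.arg(transform)
  mat <- if (is(x, "CoreAssemblage")) abundanceMatrix(x) else as.matrix(x)
  if (any(rowSums(mat) == 0) && transform != "none")
    stop("empty increments cannot be transformed to relative abundances")
  mat <- switch(transform,
    sqrt_rel = sqrt(mat / rowSums(mat)),
    rel = mat / rowSums(mat),
    none = mat
  )
  vegan::vegdist(mat, method = "bray")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the squared
#' distances by the grouping factor, reports the pseudo-F, and derives the
#' p-value from seeded free permutation of the group labels (resolution
#' `1/(nPermutations + 1)`).
#'
#' @param d a `dist` object.
#' @param groups grouping vector (one label per object in `d`).
#' @param nPermutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame with `pseudo_f`, `r2`, `p_value`, `n_permutations`,
#'   `df_between`, `df_within`.
#' @export
permanovaTest <- function(d, groups, nPermutations = 999L, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("groups must have one label per object in the distance matrix")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 members for PERMANOVA")
  df <- data.frame(grp = groups)
  fit <- withr_seed(seed,
    vegan::adonis2(d ~ grp, data = df, permutations = nPermutations))
  data.frame(
    pseudo_f = fit$F[1],
    r2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = nPermutations,
    df_between = fit$Df[1],
    df_within = fit$Df[2]
  )
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS, best of `starts` seeded random initializations.
#' The configuration is determined only up to rotation and reflection;
#' compare configurations with Procrustes methods, not coordinate-wise.
#'
#' @param d a `dist` object.
#' @param dims embedding dimensions (default 2).
#' @param starts random starts (default 50).
#' @param seed RNG seed.
#' @return list with `method`, `scores` (sites x dims), `stress` (in
#'   `[0, 1]`), `converged`.
#' @export
nmdsOrdination <- function(d, dims = 2L, starts = 50L, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  fit <- withr_seed(seed,
    vegan::metaMDS(d, k = dims, try = starts, trymax = starts, trace = 0,
                   wascores = FALSE))
  list(method = "NMDS", scores = vegan::scores(fit, display = "sites"),
       stress = fit$stress, converged = isTRUE(fit$converged))
}

#' Forward-selection redundancy analysis
#'
#' Constrained ordination of a community matrix on environmental covariates
#' with forward model selection: at each step the candidate covariate whose
#' addition yields the largest gain in adjusted R-squared is tested by a
#' seeded permutation test (conditioning on the covariates already
#' selected) and admitted only if `p <= alpha` and the gain is positive;
#' selection stops when no candidate passes. The community matrix receives
#' the same square-root relative-abundance transform as the NMDS chain.
#'
#' @param response a `CoreAssemblage` or increments-by-taxa matrix.
#' @param covariates data.frame of candidate covariates, rows aligned with
#'   the increments of `response`.
#' @param alpha admission level (default 0.05).
#' @param nPermutations permutations per admission test (default 10000).
#' @param seed RNG seed.
#' @param transform transform for the response, see [brayCurtisDist()].
#' @return list with `method = "RDA"`, `selected` (data.frame: step,
#'   variable, adjusted R2 of the cumulative model, gain, p-value),
#'   `model` (the final vegan rda, or NULL if nothing was selected),
#'   `scores` (site scores of the final model), `varianceFractions`
#'   (constrained / unconstrained / total inertia).
#' @export
rdaForwardSelect <- function(response, covariates, alpha = 0.05,
                             nPermutations = 10000L, seed = 1L,
                             transform = "sqrt_rel") {
  mat <- if (is(response, "CoreAssemblage")) abundanceMatrix(response)
         else as.matrix(response)
  transform <- match.arg(transform, c("sqrt_rel", "rel", "none"))
  if (transform != "none") {
    if (any(rowSums(mat) == 0))
      stop("empty increments cannot be transformed to relative abundances")
    mat <- mat / rowSums(mat)
    if (transform == "sqrt_rel") mat <- sqrt(mat)
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(mat))
  candidates <- names(covariates)
  selected <- character(0)
  steps <- list()
  adjNow <- 0
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    adj <- vapply(remaining, function(v) {
      f <- stats::as.formula(paste("mat ~", paste(c(selected, v), collapse = "+")))
      vegan::RsquareAdj(vegan::rda(f, data = covariates))$adj.r.squared
    }, numeric(1))
    bestVar <- remaining[which.max(adj)]
    gain <- max(adj) - adjNow
    if (!is.finite(gain) || gain <= 0) break
    # admission test: partial RDA of the candidate given the selected set
    f <- if (length(selected)) {
      stats::as.formula(paste("mat ~", bestVar, "+ Condition(",
                              paste(selected, collapse = "+"), ")"))
    } else stats::as.formula(paste("mat ~", bestVar))
    mod <- vegan::rda(f, data = covariates)
    an <- withr_seed(seed + length(selected),
      vegan::anova.cca(mod, permutations = nPermutations))
    p <- an$`Pr(>F)`[1]
    if (is.na(p) || p > alpha) break
    selected <- c(selected, bestVar)
    adjNow <- max(adj)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(selected), variable = bestVar,
      adj_r2 = adjNow, gain = gain, p_value = p)
  }
  selTab <- if (length(steps)) do.call(rbind, steps)
            else data.frame(step = integer(), variable = character(),
                            adj_r2 = numeric(), gain = numeric(),
                            p_value = numeric())
  model <- NULL; scores <- NULL; fractions <- NULL
  if (length(selected)) {
    f <- stats::as.formula(paste("mat ~", paste(selected, collapse = "+")))
    model <- vegan::rda(f, data = covariates)
    scores <- vegan::scores(model, display = "sites")
    fractions <- c(constrained = model$CCA$tot.chi,
                   unconstrained = model$CA$tot.chi,
                   total = model$tot.chi)
  }
  list(method = "RDA", selected = selTab, model = model, scores = scores,
       varianceFractions = fractions)
}
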