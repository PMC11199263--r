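#' Global field power
#'
#' GFP(t) is the population standard deviation (divisor N) across channels
#' of the topography at time t. Peaks of the GFP series mark moments of
#' highest topographic signal-to-noise and are the samples submitted to
#' clustering.
#'
#' @param rec An [ms_recording()] (average-referenced) or a bare
#'   channels x samples matrix.
#' @return Numeric vector, one non-negative value per sample.
#' @export
gfp <- function(rec) {
  X <- if (inherits(rec, "ms_recording")) rec$data else as.matrix(rec)
  X <- sweep(X, 2L, colMeans(X), "-")
  sqrt(colMeans(X^2))
}

#' Extract topographies at GFP peaks
#'
#' A peak is an interior sample t with `GFP(t-1) < GFP(t) >= GFP(t+1)`;
#' the strict left inequality keeps only the first sample of a plateau.
#' Endpoints are never peaks. An optional minimum separation (default 0 =
#' off) greedily keeps the highest peaks first and drops any peak closer
#' than the separation to one already kept.
#'
#' @param rec An [ms_recording()] with at least 3 samples.
#' @param min_separation_ms Minimum distance between kept peaks, in ms.
#' @return A list: `indices` (1-based sample indices), `topographies`
#'   (channels x n_peaks matrix), `gfp` (GFP at the peaks).
#' @export
extract_gfp_peaks <- function(rec, min_separation_ms = 0) {
  stopifnot(inherits(rec, "ms_recording"), n_samples(rec) >= 3L)
  g <- gfp(rec)
  n <- length(g)
  t_ <- 2:(n - 1L)
  is_peak <- g[t_ - 1L] < g[t_] & g[t_] >= g[t_ + 1L]
  idx <- t_[is_peak]
  if (min_separation_ms > 0 && length(idx) > 1L) {
    sep <- round(min_separation_ms * rec$srate / 1000)
    ord <- idx[order(g[idx], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) if (!length(kept) || min(abs(kept - i)) >= sep)
      kept <- c(kept, i)
    idx <- sort(kept)
  }
  list(indices = idx,
       topographies = rec$data[, idx, drop = FALSE],
       gfp = g[idx])
}

#' Polarity-invariant modified k-means
#'
#' Clusters sample topographies into k sign-arbitrary maps. Samples are
#' centred and unit-normalized internally; each repeat initializes the
#' maps from k distinct samples drawn uniformly, assigns every sample to
#' the map with the largest squared spatial correlation (polarity
#' ignored), and re-estimates each map as the principal eigenvector of the
#' scatter (sum of outer products) of its assigned samples, until the
#' relative change in global explained variance (GEV) drops below `tol`
#' or `max_iter` is reached. The best of `n_repeats` by GEV is kept. Empty
#' clusters are re-seeded deterministically from the worst-fitted sample.
#'
#' GEV is the GFP-squared-weighted mean squared spatial correlation
#' between each sample and its assigned map.
#'
#' @param samples Channels x M matrix of topographies.
#' @param k Number of clusters (`k <= M`).
#' @param n_repeats Number of random restarts.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative GEV change below which a restart stops.
#' @param seed Integer seed for the restarts' initial samples.
#' @param weights Optional per-sample GEV weights; default is the squared
#'   norm of each (centred) sample, i.e. proportional to squared GFP.
#' @return A list: `maps` (an [ms_maps()]), `assignment` (length M,
#'   1..k), `fit` (per-sample squared correlation with the assigned map),
#'   `gev`.
#' @export
modified_kmeans <- function(samples, k, n_repeats = 50L, max_iter = 200L,
                            tol = 1e-7, seed = 1L, weights = NULL) {
  X <- as.matrix(samples)
  uc <- unit_columns(X)
  if (any(!uc$nonzero)) stop("samples include all-zero topographies")
  M <- ncol(X)
  if (k > M) stop("k = ", k, " exceeds the number of samples (", M, ")")
  w2 <- if (is.null(weights)) uc$norm^2 else as.numeric(weights)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  inits <- vapply(seq_len(n_repeats),
                  function(i) sample.int(M, k) - 1L,
                  integer(k))
  inits <- matrix(as.integer(inits), nrow = k)
  res <- mk_kmeans_core(uc$u, w2, as.integer(k), inits,
                        as.integer(max_iter), tol)
  maps <- ms_maps(t(res$maps))
  list(maps = maps, assignment = as.integer(res$assignment),
       fit = as.numeric(res$fit), gev = res$gev)
}

# Subsample size so that any given sample appears in at least one of
# n_epochs subsamples with probability coverage_target.
subsample_size <- function(M, n_epochs, coverage_target = 0.999) {
  as.integer(ceiling(M * (1 - (1 - coverage_target)^(1 / n_epochs))))
}

#' Resampled clustering over a range of k
#'
#' Draws `n_epochs` random subsamples (without replacement) of the input
#' topographies, each of size `m = ceiling(M * (1 - (1 -
#' coverage_target)^(1/n_epochs)))` so that every sample has probability
#' `coverage_target` of entering at least one epoch. Each epoch is
#' clustered over `k_range` with [modified_kmeans()] and, when
#' `select = TRUE`, its optimal k is chosen automatically by the
#' meta-criterion.
#'
#' @param samples Channels x M matrix.
#' @param k_range Integer vector of candidate cluster counts.
#' @param n_epochs Number of resampling epochs.
#' @param coverage_target Probability that a sample enters >= 1 epoch.
#' @param n_repeats Restarts per [modified_kmeans()] run.
#' @param seed Integer seed; per-epoch seeds are derived with
#'   [derive_seed()].
#' @param select Choose each epoch's k by the meta-criterion (TRUE) or
#'   return all k (FALSE).
#' @param weights Optional per-sample GEV weights (see
#'   [modified_kmeans()]).
#' @return A list with `epochs` (per epoch: `chosen_k`, `maps`,
#'   `gev_curve`, `meta`), `m` (subsample size), `k_range`.
#' @export
resampled_clustering <- function(samples, k_range = 1:12, n_epochs = 50L,
                                 coverage_target = 0.999, n_repeats = 50L,
                                 seed = 1L, select = TRUE, weights = NULL) {
  X <- as.matrix(samples)
  M <- ncol(X)
  m <- subsample_size(M, n_epochs, coverage_target)
  if (m < max(k_range))
    stop("subsample size ", m, " is smaller than max(k_range) = ",
         max(k_range))
  if (!is.null(weights)) weights <- as.numeric(weights)
  epochs <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    eseed <- derive_seed(seed, "epoch", e)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(eseed)
    idx <- sort(sample.int(M, m))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    sub <- X[, idx, drop = FALSE]
    wsub <- if (is.null(weights)) NULL else weights[idx]
    fits <- lapply(k_range, function(k)
      modified_kmeans(sub, k, n_repeats = n_repeats,
                      seed = derive_seed(eseed, "k", k), weights = wsub))
    names(fits) <- as.character(k_range)
    gev_curve <- vapply(fits, `[[`, numeric(1L), "gev")
    if (select && length(k_range) > 1L) {
      curves <- validity_curves(sub, fits, k_range)
      meta <- meta_criterion(curves, k_range)
      chosen <- meta$chosen_k
    } else {
      meta <- NULL
      chosen <- k_range[which.max(gev_curve)]
    }
    epochs[[e]] <- list(chosen_k = chosen,
                        maps = fits[[as.character(chosen)]]$maps,
                        gev_curve = gev_curve,
                        meta = meta)
  }
  list(epochs = epochs, m = m, k_range = k_range)
}

#' Cluster validity criteria on the polarity-invariant dissimilarity
#'
#' Computes six standard internal validity criteria on the dissimilarity
#' `d(u, v) = sqrt(1 - corr(u, v)^2)` (spatial correlation squared, so
#' polarity is ignored): Hubert's Gamma, mean silhouette width,
#' Davies-Bouldin (sign-inverted so that larger is better), point-biserial
#' correlation, Dunn's index, and Krzanowski-Lai. Krzanowski-Lai compares
#' within-cluster dispersion across neighbouring k and is only defined
#' with that context (supplied automatically by [validity_curves()]);
#' in a standalone call it is `NA`.
#'
#' @param samples Channels x M matrix.
#' @param assignment Integer vector of cluster labels 1..k.
#' @param maps The k cluster maps ([ms_maps()] or matrix, rows = maps).
#' @param D Optional precomputed M x M dissimilarity matrix.
#' @param kl_context Optional Krzanowski-Lai value computed with cross-k
#'   context by [validity_curves()].
#' @param d2sum Optional precomputed `sum(D^2)/2` (shared across k).
#' @param stats Optional precomputed pair statistics (internal; shared
#'   single-pass computation by [validity_curves()]).
#' @return Named numeric vector of the six criteria (larger = better)
#'   plus attribute `"W"`, the within-cluster dispersion used by
#'   Krzanowski-Lai.
#' @export
cluster_validity_criteria <- function(samples, assignment, maps, D = NULL,
                                      kl_context = NULL, d2sum = NULL,
                                      stats = NULL) {
  X <- as.matrix(samples)
  U <- unit_columns(X)$u
  lab <- as.integer(assignment)
  M <- ncol(U)
  if (is.null(D)) D <- dissim_from_cross(crossprod(U))
  Mu <- if (inherits(maps, "ms_maps")) maps$maps else as.matrix(maps)
  Mu <- Mu - rowMeans(Mu)
  Mu <- Mu / sqrt(rowSums(Mu^2))
  k <- nrow(Mu)
  if (k < 2L) stop("validity criteria require k >= 2")

  # sample-to-own-map dissimilarity, within-cluster dispersion
  cross2 <- (Mu %*% U)^2                     # k x M squared correlations
  d_own <- sqrt(pmax(0, 1 - cross2[cbind(lab, seq_len(M))]))
  W <- sum(d_own^2)

  st <- if (is.null(stats)) criteria_stats_core(D, lab - 1L, as.integer(k))
        else stats
  n_pairs <- st$n_within + st$n_between
  if (st$n_within == 0 || st$n_between == 0 || any(st$counts < 2)) {
    # degenerate partition: an empty or singleton cluster is not a
    # credible microstate class, so every criterion takes its worst value
    out <- c(gamma_hubert = 0, silhouette = -1, davies_bouldin_inv = -Inf,
             point_biserial = 0, dunn = 0, krzanowski_lai = NA_real_)
    attr(out, "W") <- W
    return(out)
  }

  mean_d <- (st$sum_within + st$sum_between) / n_pairs
  if (is.null(d2sum)) d2sum <- sum(D^2) / 2
  var_d <- d2sum / n_pairs - mean_d^2          # population variance of d
  p_between <- st$n_between / n_pairs
  # Hubert Gamma: correlation of d with the between-cluster indicator
  gamma <- if (var_d > 0)
    (st$sum_between / n_pairs - mean_d * p_between) /
      sqrt(var_d * p_between * (1 - p_between)) else 0

  sil <- st$silhouette

  # Davies-Bouldin with the cluster maps as centres, inverted
  S <- vapply(seq_len(k), function(c)
    if (any(lab == c)) mean(d_own[lab == c]) else 0, numeric(1L))
  Dm <- sqrt(pmax(1 - tcrossprod(Mu)^2, 0))
  db <- mean(vapply(seq_len(k), function(i) {
    r <- (S[i] + S[-i]) / pmax(Dm[i, -i], 1e-12)
    max(r)
  }, numeric(1L)))

  mw <- st$sum_within / st$n_within
  mb <- st$sum_between / st$n_between
  pb <- if (var_d > 0)
    (mb - mw) * sqrt((1 - p_between) * p_between) / sqrt(var_d) else 0

  # Dunn: min between-cluster distance over max within-cluster diameter
  dunn <- st$min_between / max(st$max_within, 1e-12)

  kl <- if (is.null(kl_context)) NA_real_ else kl_context

  out <- c(gamma_hubert = gamma, silhouette = sil,
           davies_bouldin_inv = -db, point_biserial = pb, dunn = dunn,
           krzanowski_lai = kl)
  attr(out, "W") <- W
  out
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Within-cluster dispersion for k = 1 (all samples on the principal axis).
dispersion_k1 <- function(U) {
  e <- eigen(tcrossprod(U), symmetric = TRUE)
  m <- e$vectors[, 1L]
  sum(1 - as.numeric(crossprod(m, U))^2)
}

#' Validity-criterion curves over a k range
#'
#' Evaluates [cluster_validity_criteria()] for every k in `k_range` from a
#' list of [modified_kmeans()] fits, sharing one pairwise dissimilarity
#' matrix and supplying the cross-k context needed by Krzanowski-Lai
#' (`KL(k) = |DIFF(k)| / |DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)`, p = number of channels;
#' undefined at the ends of the range).
#'
#' @param samples Channels x M matrix.
#' @param fits Named list of fits (one per k, names = k).
#' @param k_range Integer vector matching `fits`.
#' @return Numeric matrix, 6 criteria x length(k_range). Values for k = 1
#'   are `NA` (handled by [meta_criterion()]).
#' @export
validity_curves <- function(samples, fits, k_range) {
  X <- as.matrix(samples)
  U <- unit_columns(X)$u
  D <- dissim_from_cross(crossprod(U))
  d2sum <- sum(D^2) / 2
  p <- nrow(X)
  crit_names <- c("gamma_hubert", "silhouette", "davies_bouldin_inv",
                  "point_biserial", "dunn", "krzanowski_lai")
  out <- matrix(NA_real_, 6L, length(k_range),
                dimnames = list(crit_names, as.character(k_range)))
  W <- numeric(length(k_range) + 1L)  # W[j] corresponds to k_range[j]
  # dispersion at k-1 below range start, for DIFF at the first k
  k_lo <- min(k_range)
  W_before <- if (k_lo >= 2L) {
    f <- modified_kmeans(X, k_lo - 1L, n_repeats = 5L, seed = 911L)
    sum(1 - f$fit)
  } else NA_real_
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    if (k < 2L) { W[j] <- dispersion_k1(U); next }
    f <- fits[[as.character(k)]]
    cv <- cluster_validity_criteria(X, f$assignment, f$maps, D = D,
                                    d2sum = d2sum)
    out[, j] <- cv
    W[j] <- attr(cv, "W")
  }
  # Krzanowski-Lai from the dispersion curve
  diff_at <- function(j) {
    k <- k_range[j]
    W_km1 <- if (j > 1L && k_range[j - 1L] == k - 1L) W[j - 1L]
             else if (k - 1L == 0L) NA_real_
             else if (j == 1L) W_before else NA_real_
    if (!is.finite(W_km1)) return(NA_real_)
    (k - 1L)^(2 / p) * W_km1 - k^(2 / p) * W[j]
  }
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    if (k < 2L || j == length(k_range)) next
    d1 <- diff_at(j); d2 <- diff_at(j + 1L)
    if (is.finite(d1) && is.finite(d2) && abs(d2) > 1e-12)
      out["krzanowski_lai", j] <- abs(d1) / abs(d2)
  }
  out
}

#' Meta-criterion: aggregate model-order selection
#'
#' Rescales each validity-criterion curve to `[0, 1]` across the searched
#' k range, takes the median of the six rescaled values at each k (so no
#' single criterion can dominate), and picks the k with the largest
#' aggregate; ties go to the smaller k. Criteria that are undefined at a
#' given k contribute 0 after rescaling; a k of 1 is assigned aggregate 0
#' so it can never win unless it is the only candidate. If every curve is
#' flat the smallest k is returned with `flat = TRUE`.
#'
#' @param curves Criteria x k matrix from [validity_curves()].
#' @param k_range Integer vector matching the columns of `curves`.
#' @return A list: `chosen_k`, `aggregate` (per k), `rescaled` (matrix),
#'   `flat`.
#' @export
meta_criterion <- function(curves, k_range) {
  stopifnot(ncol(curves) == length(k_range))
  if (sum(is.finite(colSums(curves, na.rm = TRUE))) < 1L ||
      length(k_range) < 2L)
    stop("need criteria at >= 2 values of k")
  resc <- t(apply(curves, 1L, function(x) {
    fin <- is.finite(x)
    if (!any(fin)) return(rep(0, length(x)))
    rng <- range(x[fin])
    out <- if (diff(rng) < 1e-15) rep(0.5, length(x))
           else (x - rng[1L]) / diff(rng)
    out[!fin] <- 0
    out
  }))
  aggregate <- apply(resc, 2L, stats::median)
  aggregate[k_range == 1L] <- 0
  flat <- stats::sd(aggregate) < 1e-15
  chosen <- if (flat) min(k_range) else k_range[which.max(aggregate)]
  list(chosen_k = chosen, aggregate = aggregate, rescaled = resc,
       flat = flat)
}

#' Individual-level clustering of one recording
#'
#' Stage 1 of the analysis: extracts GFP-peak topographies and runs
#' [resampled_clustering()] with automatic per-epoch model-order
#' selection, yielding one optimal topography set per resampling epoch.
#'
#' @param rec An average-referenced [ms_recording()].
#' @param k_range,n_epochs,coverage_target,n_repeats,seed Passed to
#'   [resampled_clustering()].
#' @param min_separation_ms Optional minimum GFP-peak separation (see
#'   [extract_gfp_peaks()]); merges noise-split duplicate peaks.
#' @return A list: `epoch_maps` (list of [ms_maps()]), `chosen_ks`,
#'   `n_peaks`, `resampling` (full [resampled_clustering()] result).
#' @export
individual_clustering <- function(rec, k_range = 1:12, n_epochs = 50L,
                                  coverage_target = 0.999, n_repeats = 50L,
                                  seed = 1L, min_separation_ms = 0) {
  peaks <- extract_gfp_peaks(rec, min_separation_ms = min_separation_ms)
  rs <- resampled_clustering(peaks$topographies, k_range = k_range,
                             n_epochs = n_epochs,
                             coverage_target = coverage_target,
                             n_repeats = n_repeats, seed = seed)
  list(epoch_maps = lapply(rs$epochs, `[[`, "maps"),
       chosen_ks = vapply(rs$epochs, `[[`, numeric(1L), "chosen_k"),
       n_peaks = length(peaks$indices),
       resampling = rs)
}

#' Group-level clustering
#'
#' Stage 2: pools every subject's per-epoch optimal maps as the sample
#' set, runs [resampled_clustering()] (per-epoch model order chosen by
#' the meta-criterion), pools the per-epoch optima again, and clusters
#' that pool once more over `k_range` in a final pass. The meta-criterion
#' curve of the final pass guides the choice of k: by default its argmax
#' is used, but `force_k` overrides it, reflecting that group-level model
#' order is a researcher decision informed (not dictated) by the
#' criterion.
#'
#' @param individual_results List of [individual_clustering()] results
#'   (or a bare list of [ms_maps()]).
#' @param k_range Candidate group-level cluster counts.
#' @param n_epochs,coverage_target,n_repeats,seed Resampling parameters.
#' @param force_k Optional explicit number of group maps.
#' @return A list of class `ms_group_result`: `maps` (chosen
#'   [ms_maps()]), `chosen_k`, `meta`, `criteria` (curves of the final
#'   pass), `gev_curve`, `per_k` (final-pass fits), `n_pooled`,
#'   `inter_map_corr` (absolute correlation matrix of the chosen maps,
#'   for transition-state screening by the analyst).
#' @export
group_level_clustering <- function(individual_results, k_range = 1:15,
                                   n_epochs = 100L, coverage_target = 0.999,
                                   n_repeats = 100L, seed = 1L,
                                   force_k = NULL) {
  pool_maps <- function(x) {
    if (inherits(x, "ms_maps")) return(list(x$maps))
    if (is.list(x) && !is.null(x$epoch_maps))
      return(lapply(x$epoch_maps, `[[`, "maps"))
    lapply(x, function(e) if (inherits(e, "ms_maps")) e$maps else e)
  }
  mats <- unlist(lapply(individual_results, pool_maps), recursive = FALSE)
  pooled <- do.call(rbind, mats)          # maps x channels
  samples <- t(pooled)
  if (ncol(samples) < max(k_range))
    stop("only ", ncol(samples), " pooled maps for max k = ", max(k_range))
  rs <- resampled_clustering(samples, k_range = k_range,
                             n_epochs = n_epochs,
                             coverage_target = coverage_target,
                             n_repeats = n_repeats,
                             seed = derive_seed(seed, "group-epochs"))
  optima <- do.call(rbind, lapply(rs$epochs, function(e) e$maps$maps))
  final_samples <- t(optima)
  k_max_ok <- min(max(k_range), ncol(final_samples))
  k_final <- k_range[k_range <= k_max_ok]
  fits <- lapply(k_final, function(k)
    modified_kmeans(final_samples, k, n_repeats = n_repeats,
                    seed = derive_seed(seed, "group-final", k)))
  names(fits) <- as.character(k_final)
  gev_curve <- vapply(fits, `[[`, numeric(1L), "gev")
  curves <- validity_curves(final_samples, fits, k_final)
  meta <- meta_criterion(curves, k_final)
  chosen <- if (!is.null(force_k)) as.integer(force_k) else meta$chosen_k
  if (!chosen %in% k_final)
    stop("force_k = ", chosen, " is outside the searched range")
  maps <- fits[[as.character(chosen)]]$maps
  maps$provenance <- list(level = "group", chosen_k = chosen, seed = seed,
                          forced = !is.null(force_k))
  structure(list(maps = maps, chosen_k = chosen, meta = meta,
                 criteria = curves, gev_curve = gev_curve, per_k = fits,
                 n_pooled = ncol(samples),
                 inter_map_corr = abs_spatial_corr_matrix(maps$maps,
                                                          maps$maps)),
            class = "ms_group_result")
}
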