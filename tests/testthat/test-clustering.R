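test_that("gfp matches the population SD across channels", {
  montage <- make_montage(4L)
  # constant column is zero after average reference
  rec <- average_reference(ms_recording(matrix(3, 4, 2), 250, montage))
  expect_equal(gfp(rec), c(0, 0))
  two <- ms_recording(matrix(c(1, -1), 2, 1), 250, make_montage(2L),
                      is_avg_ref = TRUE)
  expect_equal(gfp(two), 1)
  big <- fixture_recording(n_channels = 105L, n_samples = 100L)
  oracle <- apply(big$data, 2L, function(col) {
    col <- col - mean(col)
    sqrt(sum(col^2) / length(col))
  })
  expect_equal(gfp(big), oracle, tolerance = 1e-12)
})

test_that("GFP peak extraction finds strict local maxima", {
  montage <- make_montage(2L)
  mk <- function(g) ms_recording(rbind(g, -g), 1000, montage,
                                 is_avg_ref = TRUE)
  # gfp of rbind(g, -g) equals |g|
  pk <- extract_gfp_peaks(mk(c(1, 3, 2, 5, 4)))
  expect_identical(pk$indices, c(2L, 4L))
  expect_identical(extract_gfp_peaks(mk(1:10))$indices, integer(0))
  # plateau: keep the first sample
  expect_identical(extract_gfp_peaks(mk(c(1, 2, 2, 2, 1)))$indices, 2L)
  # 10 Hz envelope: |sin| has two maxima per cycle, ~20 peaks per second
  spec <- synth_spec(n_channels = 32L, seed = 2L, snr = 1e6)
  maps <- generate_prototype_maps(2L, make_montage(32L), seed = 2L)
  lab <- rep(1L, 250L)  # one segment: a single continuous sinusoid
  gr <- generate_recording(maps, lab, spec, seed = 4L)
  n_pk <- length(extract_gfp_peaks(gr$rec)$indices)
  expect_gte(n_pk, 18L); expect_lte(n_pk, 22L)
})

test_that("modified k-means recovers noiseless generators exactly", {
  set.seed(10)
  N <- 24L
  m1 <- rnorm(N); m1 <- m1 - mean(m1); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- rnorm(N); m2 <- m2 - mean(m2)
  m2 <- m2 - sum(m2 * m1) * m1; m2 <- m2 / sqrt(sum(m2^2))
  amp <- runif(60, 0.5, 2) * sample(c(-1, 1), 60, TRUE)
  X <- cbind(outer(m1, amp[1:30]), outer(m2, amp[31:60]))
  fit <- modified_kmeans(X, 2L, n_repeats = 5L, seed = 1L)
  C <- abs_spatial_corr_matrix(fit$maps$maps, rbind(m1, m2))
  expect_equal(max(C[1, ]), 1, tolerance = 1e-9)
  expect_equal(max(C[2, ]), 1, tolerance = 1e-9)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  # polarity invariance: sign-flipping every sample changes nothing
  flip <- modified_kmeans(-X, 2L, n_repeats = 5L, seed = 1L)
  expect_identical(flip$assignment, fit$assignment)
  expect_equal(flip$gev, fit$gev, tolerance = 0)
  expect_equal(flip$maps$maps, fit$maps$maps, tolerance = 0)
})

test_that("k = 1 reduces to the principal component of the scatter", {
  X0 <- fixture_recording(n_channels = 12L, n_samples = 40L, seed = 3L)$data
  X <- microstates:::unit_columns(X0)$u   # unit-norm samples: weights even
  fit <- modified_kmeans(X, 1L, n_repeats = 2L, seed = 1L)
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  pc1 <- e$vectors[, 1L]
  expect_equal(abs(sum(fit$maps$maps[1, ] * pc1)), 1, tolerance = 1e-9)
  # GEV equals the normalized leading eigenvalue share of the scatter
  expect_equal(fit$gev, e$values[1L] / sum(e$values), tolerance = 1e-9)
})

test_that("GEV is non-decreasing in k on a fixed sample set", {
  spec <- synth_spec(n_channels = 32L, n_subjects = 1L, minutes = 0.25,
                     seed = 21L)
  coh <- generate_cohort(spec)
  pk <- extract_gfp_peaks(coh$recordings[[1L]])
  gev <- vapply(1:8, function(k)
    modified_kmeans(pk$topographies, k, n_repeats = 10L, seed = 5L)$gev,
    numeric(1L))
  expect_true(all(diff(gev) > -1e-9))
})

test_that("resampling subsample sizes follow the coverage formula", {
  expect_identical(microstates:::subsample_size(1000L, 1L, 0.999),
                   as.integer(ceiling(0.999 * 1000)))
  expect_identical(microstates:::subsample_size(10000L, 50L, 0.999), 1291L)
  # identical seeds give identical epochs
  X <- fixture_recording(n_channels = 8L, n_samples = 120L, seed = 2L)$data
  a <- resampled_clustering(X, k_range = 2:3, n_epochs = 3L, n_repeats = 3L,
                            seed = 9L)
  b <- resampled_clustering(X, k_range = 2:3, n_epochs = 3L, n_repeats = 3L,
                            seed = 9L)
  expect_identical(lapply(a$epochs, `[[`, "chosen_k"),
                   lapply(b$epochs, `[[`, "chosen_k"))
  expect_identical(a$epochs[[1L]]$maps$maps, b$epochs[[1L]]$maps$maps)
  expect_error(resampled_clustering(X, k_range = 2:119, n_epochs = 50L),
               "subsample size")
})

test_that("validity criteria separate good partitions from bad ones", {
  set.seed(33)
  N <- 16L
  mk_unit <- function() {
    v <- rnorm(N); v <- v - mean(v); v / sqrt(sum(v^2))
  }
  m1 <- mk_unit(); m2 <- mk_unit()
  jitter_of <- function(m) {
    v <- m + rnorm(N, sd = 0.003); v <- v - mean(v); v / sqrt(sum(v^2))
  }
  X <- cbind(replicate(20, jitter_of(m1)), replicate(20, jitter_of(m2)))
  lab <- rep(1:2, each = 20L)
  maps <- rbind(m1, m2)
  cv <- cluster_validity_criteria(X, lab, maps)
  expect_gte(cv[["silhouette"]], 0.95)
  expect_gt(cv[["gamma_hubert"]], 0.9)
  expect_gt(cv[["dunn"]], 1)
  # silhouette agrees with the cluster package on arbitrary labelings
  set.seed(34)
  Y <- matrix(rnorm(N * 30), N, 30)
  laby <- sample(1:3, 30, TRUE)
  mapsy <- rbind(mk_unit(), mk_unit(), mk_unit())
  U <- microstates:::unit_columns(Y)$u
  D <- sqrt(pmax(1 - crossprod(U)^2, 0))
  ours <- cluster_validity_criteria(Y, laby, mapsy, D = D)
  ref <- mean(cluster::silhouette(laby, dmatrix = D)[, "sil_width"])
  expect_equal(ours[["silhouette"]], ref, tolerance = 1e-10)
  # random labels on homogeneous data: silhouette near zero
  sils <- vapply(1:20, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(N * 40), N, 40)
    labz <- sample(1:2, 40, TRUE)
    mz <- rbind(mk_unit(), mk_unit())
    cluster_validity_criteria(Z, labz, mz)[["silhouette"]]
  }, numeric(1L))
  expect_lte(abs(mean(sils)), 0.1)
})

test_that("the meta-criterion aggregates by median and resists one rogue curve", {
  k_range <- 2:8
  flat <- rep(0.5, 7)
  peak5 <- c(0.1, 0.2, 0.3, 1.0, 0.3, 0.2, 0.1)
  curves <- rbind(flat, flat, flat, flat, flat, peak5)
  m <- meta_criterion(curves, k_range)
  expect_false(m$chosen_k == 5L)  # a single criterion cannot dominate
  curves4 <- do.call(rbind, replicate(6, c(0.2, 0.5, 1.0, 0.4, 0.3, 0.2, 0.1),
                                      simplify = FALSE))
  expect_identical(meta_criterion(curves4, k_range)$chosen_k, 4L)
  # ties resolve to the smaller k
  tied <- do.call(rbind, replicate(6, c(0, 1, 1, 0, 0, 0, 0),
                                   simplify = FALSE))
  expect_identical(meta_criterion(tied, k_range)$chosen_k, 3L)
  # flat everything: smallest k, flagged
  allflat <- matrix(0.5, 6, 7)
  mf <- meta_criterion(allflat, k_range)
  expect_identical(mf$chosen_k, 2L)
  expect_true(mf$flat)
  # k = 1 can never win
  curves1 <- cbind(rep(NA_real_, 6), curves4)
  m1 <- meta_criterion(curves1, 1:8)
  expect_identical(m1$aggregate[[1L]], 0)
  expect_false(m1$chosen_k == 1L)
})

test_that("map matching recovers permutations and beats random pairings", {
  maps <- generate_prototype_maps(5L, make_montage(32L), seed = 12L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  flipped <- maps$maps[perm, ] * c(1, -1, 1, -1, 1)
  mm <- match_maps(maps, ms_maps(flipped))
  expect_equal(mm$pairs$abs_corr, rep(1, 5), tolerance = 1e-9)
  expect_identical(mm$pairs$b[order(mm$pairs$a)], order(perm))
  ident <- match_maps(maps, maps)
  expect_identical(ident$pairs$b, 1:5)
  # total correlation at least as good as any random pairing
  set.seed(44)
  noisy <- ms_maps(maps$maps + matrix(rnorm(5 * 32, sd = 0.2), 5, 32))
  mm2 <- match_maps(maps, noisy)
  C <- abs_spatial_corr_matrix(maps$maps, noisy$maps)
  for (i in 1:100) {
    p <- sample(5L)
    expect_gte(mm2$total_corr + 1e-12, sum(C[cbind(1:5, p)]))
  }
})

test_that("the Hungarian solver agrees with exhaustive enumeration", {
  set.seed(55)
  for (trial in 1:20) {
    n <- sample(3:6, 1L)
    S <- matrix(runif(n * n), n, n)
    hung <- microstates:::hungarian_max(S)
    perms <- microstates:::permutations(n)
    best <- -Inf
    for (p in seq_len(nrow(perms)))
      best <- max(best, sum(S[cbind(seq_len(n), perms[p, ])]))
    expect_equal(sum(S[cbind(seq_len(n), hung)]), best, tolerance = 1e-12)
  }
  # rectangular case
  S <- matrix(runif(3 * 5), 3, 5)
  hung <- microstates:::hungarian_max(S)
  cols <- utils::combn(5L, 3L, simplify = FALSE)
  best <- -Inf
  for (cc in cols) {
    perms <- microstates:::permutations(3L)
    for (p in seq_len(nrow(perms)))
      best <- max(best, sum(S[cbind(1:3, cc[perms[p, ]])]))
  }
  expect_equal(sum(S[cbind(1:3, hung)]), best, tolerance = 1e-12)
})

test_that("group-level clustering collapses a degenerate pool to its maps", {
  maps <- generate_prototype_maps(5L, make_montage(32L), seed = 31L)
  # one subject whose epochs all contain the same 5 maps (sign-flipped
  # copies to exercise polarity handling)
  epochs <- lapply(1:6, function(e)
    ms_maps(maps$maps * sample(c(-1, 1), 5, TRUE)))
  grp <- group_level_clustering(list(epochs), k_range = 2:6, n_epochs = 5L,
                                n_repeats = 4L, seed = 3L)
  expect_identical(grp$chosen_k, 5L)
  mm <- match_maps(grp$maps, maps)
  expect_equal(mm$pairs$abs_corr, rep(1, 5), tolerance = 1e-6)
  # explicit override wins regardless of the criterion
  grp4 <- group_level_clustering(list(epochs), k_range = 2:6, n_epochs = 5L,
                                 n_repeats = 4L, seed = 3L, force_k = 4L)
  expect_identical(nrow(grp4$maps$maps), 4L)
})
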