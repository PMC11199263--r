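# Shared fixture builders: everything is generated in code at test time.

# A small recording with known content.
fixture_recording <- function(n_channels = 8L, n_samples = 100L, srate = 250,
                              seed = 1L, avg_ref = TRUE) {
  set.seed(seed)
  dat <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  rec <- ms_recording(dat, srate, make_montage(n_channels))
  if (avg_ref) rec <- average_reference(rec)
  rec
}

# A random segmentation fixture (labels, correlations, gfp) for the
# metric oracles.
fixture_segmentation <- function(n = 1000L, K = 4L, srate = 250, seed = 1L,
                                 p_unlabeled = 0.1) {
  set.seed(seed)
  labels <- integer(n)
  t <- 1L
  while (t <= n) {
    len <- sample(2:30, 1L)
    lab <- if (runif(1) < p_unlabeled) 0L else sample.int(K, 1L)
    end <- min(t + len - 1L, n)
    labels[t:end] <- lab
    t <- end + 1L
  }
  ac <- ifelse(labels == 0L, runif(n, 0, 0.5), runif(n, 0.5, 1))
  ms_segmentation(labels, ac, gfp = runif(n, 0.2, 3), srate = srate, K = K)
}

# Independent brute-force recomputation of the temporal properties from
# first principles (simple loops; no shared code with the implementation).
oracle_metrics <- function(seg, exclude_edge_segments = TRUE) {
  labels <- seg$labels; g <- seg$gfp; ac <- seg$abs_corr
  n <- length(labels); K <- seg$K
  # extract runs by scanning
  runs <- list()
  start <- 1L
  for (t in seq_len(n)) {
    if (t == n || labels[t + 1L] != labels[t]) {
      runs[[length(runs) + 1L]] <- list(state = labels[start],
                                        len = t - start + 1L,
                                        edge = start == 1L || t == n)
      start <- t + 1L
    }
  }
  out <- data.frame(state = seq_len(K), gev = 0, mean_duration_ms = NA_real_,
                    coverage = 0, occurrence = 0)
  for (k in seq_len(K)) {
    sel <- which(labels == k)
    out$coverage[k] <- length(sel) / n
    out$gev[k] <- sum((g[sel] * ac[sel])^2) / sum(g^2)
    lens <- c()
    for (r in runs)
      if (r$state == k && !(exclude_edge_segments && r$edge))
        lens <- c(lens, r$len)
    if (length(lens)) out$mean_duration_ms[k] <- mean(lens) * 1000 / seg$srate
    out$occurrence[k] <- length(lens) / (n / seg$srate)
  }
  out
}

# Independent transition counting by scanning the label sequence.
oracle_transitions <- function(seg) {
  labels <- seg$labels; K <- seg$K
  # run-level sequence
  v <- rle(labels)$values
  counts <- matrix(0, K, K)
  for (i in seq_len(length(v) - 1L)) {
    a <- v[i]; b <- v[i + 1L]
    if (a != 0L && b != 0L) counts[a, b] <- counts[a, b] + 1
  }
  obs <- counts
  for (a in seq_len(K)) if (sum(counts[a, ]) > 0)
    obs[a, ] <- counts[a, ] / sum(counts[a, ])
  segc <- sapply(seq_len(K), function(k) sum(v == k))
  expd <- matrix(0, K, K)
  for (a in seq_len(K)) {
    if (sum(segc[-a]) > 0) expd[a, ] <- segc / sum(segc[-a])
    expd[a, a] <- 0
  }
  list(counts = counts, observed = obs, expected = expd)
}

# Desk-scale two-level clustering parameters used by the recovery
# studies in the acceptance tests and the acceptance script.
desk_params <- list(
  individual = list(k_range = 2:6, n_epochs = 6L, n_repeats = 2L),
  group = list(k_range = 2:8, n_epochs = 20L, n_repeats = 8L))

# One full two-level recovery run on a synthetic cohort.
run_recovery_seed <- function(seed, n_subjects = 20L, minutes = 2,
                              params = desk_params) {
  spec <- synth_spec(n_subjects = n_subjects, minutes = minutes, seed = seed)
  coh <- generate_cohort(spec)
  ind <- lapply(seq_along(coh$recordings), function(s)
    individual_clustering(coh$recordings[[s]],
                          k_range = params$individual$k_range,
                          n_epochs = params$individual$n_epochs,
                          n_repeats = params$individual$n_repeats,
                          seed = derive_seed(seed, "ind", s)))
  grp <- group_level_clustering(ind, k_range = params$group$k_range,
                                n_epochs = params$group$n_epochs,
                                n_repeats = params$group$n_repeats,
                                seed = seed)
  mm <- match_maps(grp$maps, coh$ground_truth$maps)
  list(chosen_k = grp$chosen_k,
       mean_abs_corr = mean(mm$pairs$abs_corr),
       group = grp, cohort = coh)
}
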