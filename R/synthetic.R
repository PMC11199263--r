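#' Deterministic seed derivation
#'
#' Derives a 31-bit child seed from a master seed and an arbitrary list of
#' string/integer tags (e.g. `derive_seed(seed, "subject", 7)`). Every
#' source of randomness in the package draws its seed this way so that a
#' single master seed fixes an entire simulated cohort and analysis run.
#'
#' @param master Integer master seed.
#' @param ... Tags (coerced to character) identifying the consumer.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(as.character(as.integer(master)),
               vapply(list(...), as.character, character(1L))),
             collapse = "/")
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Quasi-uniform sensor layout on the upper part of a unit sphere
# (Fibonacci lattice over z in [-0.15, 1], mimicking scalp coverage).
hemisphere_positions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 1.15 * i / n          # from vertex down past the equator a little
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Construct a synthetic sensor montage
#'
#' Places `n_channels` sensors quasi-uniformly over the upper ~60% of a
#' unit sphere, emulating a high-density infant EEG net.
#'
#' @param n_channels Number of channels (default 105).
#' @return An [ms_montage()].
#' @export
make_montage <- function(n_channels = 105L) {
  ms_montage(paste0("E", seq_len(n_channels)),
             hemisphere_positions(n_channels))
}

#' Specification of a synthetic microstate cohort
#'
#' Collects every generative parameter of the synthetic-EEG model. The
#' defaults emulate a high-density infant resting-state study: 105
#' channels at 250 Hz, five planted microstate maps with a mean segment
#' duration of 60 ms, a 10 Hz polarity-alternating oscillatory envelope,
#' signal-to-noise ratio 4 at the GFP level, and log-normal
#' between-subject spread of 0.3 on the per-state temporal parameters.
#'
#' @param n_channels Number of channels.
#' @param srate Sampling rate (Hz).
#' @param K_true Number of planted microstate maps.
#' @param mean_duration_ms Mean microstate segment duration (ms); segment
#'   lengths are geometric (memoryless), so the planted sequence is an
#'   exact first-order Markov chain.
#' @param transition_matrix K x K row-stochastic matrix with zero
#'   diagonal; `NULL` means uniform over the other states.
#' @param snr Ratio of signal GFP RMS to noise GFP RMS (> 0).
#' @param envelope_freq_hz Frequency of the sinusoidal amplitude envelope;
#'   its sign alternation exercises polarity invariance by construction.
#' @param n_subjects Cohort size.
#' @param minutes Recording length per subject (minutes).
#' @param seed Master seed; per-subject seeds are derived with
#'   [derive_seed()].
#' @param between_subject_sd SD of the log-normal multiplicative jitter
#'   applied per subject and state to duration/occurrence parameters.
#' @param max_abs_corr Maximum absolute pairwise spatial correlation
#'   allowed between planted prototype maps.
#' @return A list of class `ms_synth_spec`.
#' @export
synth_spec <- function(n_channels = 105L, srate = 250, K_true = 5L,
                       mean_duration_ms = 60, transition_matrix = NULL,
                       snr = 4, envelope_freq_hz = 10,
                       n_subjects = 20L, minutes = 2, seed = 1L,
                       between_subject_sd = 0.3, max_abs_corr = 0.6) {
  K <- as.integer(K_true)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (K - 1), K, K)
    diag(transition_matrix) <- 0
    if (K == 1L) transition_matrix <- matrix(0, 1L, 1L)
  }
  tm <- as.matrix(transition_matrix)
  if (K > 1L) {
    if (any(abs(diag(tm)) > 0)) stop("transition matrix diagonal must be zero")
    if (any(abs(rowSums(tm) - 1) > 1e-9))
      stop("transition matrix rows must sum to 1")
  }
  if (snr <= 0) stop("snr must be > 0")
  if (mean_duration_ms <= 0) stop("mean_duration_ms must be > 0")
  structure(list(n_channels = as.integer(n_channels), srate = srate,
                 K_true = K, mean_duration_ms = mean_duration_ms,
                 transition_matrix = tm, snr = snr,
                 envelope_freq_hz = envelope_freq_hz,
                 n_subjects = as.integer(n_subjects), minutes = minutes,
                 seed = as.integer(seed),
                 between_subject_sd = between_subject_sd,
                 max_abs_corr = max_abs_corr),
            class = "ms_synth_spec")
}

# Potential of a current dipole at position p with moment q, sampled at
# sensor positions R (rows): phi(r) ~ q . (r - p) / |r - p|^3.
dipole_field <- function(R, p, q) {
  d <- sweep(R, 2L, p, "-")
  dist3 <- (sqrt(rowSums(d^2)))^3
  as.numeric(d %*% q) / pmax(dist3, 1e-6)
}

#' Generate planted prototype topographies
#'
#' Each map is the field of a small number of randomly placed and oriented
#' dipole pairs inside the head sphere, projected onto the montage, then
#' centred and unit-normalized. Maps are redrawn until all pairwise
#' absolute spatial correlations are at most `max_abs_corr`.
#'
#' @param K Number of maps.
#' @param montage An [ms_montage()].
#' @param max_abs_corr Pairwise |correlation| bound in (0, 1).
#' @param seed Integer seed (deterministic output).
#' @param max_tries Redraw budget per map before giving up.
#' @return An [ms_maps()] with K rows.
#' @export
generate_prototype_maps <- function(K, montage, max_abs_corr = 0.6,
                                    seed = 1L, max_tries = 500L) {
  stopifnot(K >= 1L, max_abs_corr > 0, max_abs_corr < 1)
  R <- montage$positions
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  draw_map <- function() {
    v <- numeric(nrow(R))
    for (d in seq_len(2L)) {  # one dipole pair
      # sources at depth: |p| <= 0.5 gives the broad scalp patterns of
      # real EEG rather than focal spikes
      repeat {
        p <- stats::runif(3, -0.5, 0.5)
        if (sum(p^2) <= 0.25) break
      }
      p[3] <- abs(p[3]) * 0.8          # keep sources in the upper head
      q <- stats::rnorm(3)
      q <- q / sqrt(sum(q^2))
      v <- v + dipole_field(R, p, q) * sample(c(-1, 1), 1L)
    }
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  maps <- matrix(0, K, nrow(R))
  i <- 1L
  tries <- 0L
  while (i <= K) {
    cand <- draw_map()
    ok <- i == 1L ||
      all(abs(maps[seq_len(i - 1L), , drop = FALSE] %*% cand) <= max_abs_corr)
    if (ok) { maps[i, ] <- cand; i <- i + 1L; tries <- 0L }
    else {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not draw ", K, " maps with pairwise |corr| <= ",
             max_abs_corr, "; use a larger montage or a looser bound")
    }
  }
  colnames(maps) <- montage$names
  ms_maps(maps, provenance = list(level = "planted", seed = seed))
}

#' Generate a planted microstate label sequence
#'
#' Segment lengths are i.i.d. geometric (support 1, 2, ...) with mean
#' `mean_duration_ms`, and each successor state is drawn from the
#' transition-matrix row of the current state, so the sequence is an exact
#' first-order Markov chain whose statistics the transition estimator can
#' recover.
#'
#' @param spec An [synth_spec()] (fields `K_true`, `mean_duration_ms`,
#'   `srate`, `transition_matrix` are used).
#' @param n_samples Sequence length.
#' @param seed Integer seed.
#' @return Integer vector of labels in `1..K`.
#' @export
generate_state_sequence <- function(spec, n_samples, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  K <- spec$K_true
  mean_len <- spec$mean_duration_ms * spec$srate / 1000
  if (mean_len < 1) stop("mean duration is below one sample")
  p <- 1 / mean_len
  labels <- integer(n_samples)
  state <- sample.int(K, 1L)
  t <- 1L
  while (t <= n_samples) {
    len <- 1L + stats::rgeom(1L, p)
    end <- min(t + len - 1L, n_samples)
    labels[t:end] <- state
    t <- end + 1L
    if (K > 1L)
      state <- sample.int(K, 1L, prob = spec$transition_matrix[state, ])
  }
  labels
}

#' Synthesize a recording from maps and a label sequence
#'
#' At sample t the signal is `maps[label(t), ] * A(t)` with
#' `A(t) = sin(2 pi f t / srate + phi_segment)` (a fresh random phase per
#' segment), plus spatially white Gaussian noise scaled so that the ratio
#' of signal GFP RMS to noise GFP RMS equals `spec$snr`. The result is
#' average-referenced and scaled to a realistic microvolt range.
#'
#' @param maps An [ms_maps()] with at least `max(labels)` rows.
#' @param labels Integer label sequence.
#' @param spec An [synth_spec()].
#' @param seed Integer seed (noise and segment phases).
#' @return A list: `rec` (an [ms_recording()]), `amplitude` (the envelope
#'   A(t)), `labels` (copied through).
#' @export
generate_recording <- function(maps, labels, spec, seed = 1L) {
  M <- maps$maps
  if (nrow(M) < max(labels)) stop("fewer maps than planted labels")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  T_ <- length(labels)
  N <- ncol(M)
  # per-segment phases
  seg_id <- cumsum(c(1L, diff(labels) != 0L))
  phi <- stats::runif(max(seg_id), 0, 2 * pi)[seg_id]
  A <- sin(2 * pi * spec$envelope_freq_hz * (seq_len(T_) - 1L) / spec$srate + phi)
  S <- t(M[labels, , drop = FALSE]) * rep(A, each = N)
  noise <- matrix(stats::rnorm(N * T_), N, T_)
  noise <- sweep(noise, 2L, colMeans(noise), "-")
  gfp_of <- function(X) sqrt(colMeans(X^2))
  rms <- function(x) sqrt(mean(x^2))
  target_noise_rms <- rms(gfp_of(S)) / spec$snr
  noise <- noise * (target_noise_rms / rms(gfp_of(noise)))
  data <- 20 * (S + noise)  # ~ tens of microvolts
  montage <- make_montage(N)
  rec <- average_reference(ms_recording(data, spec$srate, montage))
  list(rec = rec, amplitude = A, labels = labels)
}

# Perturb a group map towards a subject-specific variant with spatial
# correlation ~ U(corr_lo, corr_hi) to the group map.
perturb_map <- function(m, corr_lo = 0.92, corr_hi = 0.99) {
  target <- stats::runif(1L, corr_lo, corr_hi)
  u <- stats::rnorm(length(m))
  u <- u - mean(u)
  u <- u - sum(u * m) * m       # orthogonal to m (m is zero-mean unit-norm)
  u <- u / sqrt(sum(u^2))
  v <- target * m + sqrt(1 - target^2) * u
  v / sqrt(sum(v^2))
}

#' Generate a synthetic cohort with planted microstate structure
#'
#' Each subject receives (a) the shared prototype maps perturbed by a small
#' random rotation in channel space (subject-to-group |correlation| at
#' least 0.9), (b) per-state mean-duration and transition-propensity
#' parameters jittered by a log-normal factor with SD
#' `between_subject_sd`, and (c) an independent noise stream. All
#' randomness derives from `spec$seed` via [derive_seed()], so the same
#' master seed reproduces the cohort exactly.
#'
#' @param spec An [synth_spec()].
#' @return A list: `recordings` (list of [ms_recording()]),
#'   `ground_truth` (list with `maps`, per-subject `subject_maps`,
#'   `labels`, `amplitude`, and per-subject generative `params`),
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ms_synth_spec"), spec$n_subjects >= 1L)
  montage <- make_montage(spec$n_channels)
  proto <- generate_prototype_maps(spec$K_true, montage,
                                   max_abs_corr = spec$max_abs_corr,
                                   seed = derive_seed(spec$seed, "maps"))
  T_ <- as.integer(round(spec$minutes * 60 * spec$srate))
  recs <- vector("list", spec$n_subjects)
  labels <- vector("list", spec$n_subjects)
  amps <- vector("list", spec$n_subjects)
  smaps <- vector("list", spec$n_subjects)
  params <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sseed <- derive_seed(spec$seed, "subject", s)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(sseed)
    sd_ <- spec$between_subject_sd
    dur_mult <- if (sd_ > 0) stats::rlnorm(spec$K_true, 0, sd_) else
      rep(1, spec$K_true)
    occ_mult <- if (sd_ > 0) stats::rlnorm(spec$K_true, 0, sd_) else
      rep(1, spec$K_true)
    M <- proto$maps
    if (sd_ > 0) for (k in seq_len(spec$K_true)) M[k, ] <- perturb_map(M[k, ])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    sub_maps <- ms_maps(M, provenance = list(level = "subject", subject = s))
    # subject-specific chain: jitter transition propensities column-wise
    tm <- sweep(spec$transition_matrix, 2L, occ_mult, "*")
    if (spec$K_true > 1L) {
      tm <- tm / rowSums(tm)
      diag(tm) <- 0
    }
    sspec <- spec
    sspec$transition_matrix <- tm
    # per-state durations require a per-state geometric; approximate with
    # the state-wise mean by drawing segment lengths per segment:
    lab <- generate_state_sequence_perstate(
      sspec, T_, dur_ms = spec$mean_duration_ms * dur_mult,
      seed = derive_seed(sseed, "labels"))
    gr <- generate_recording(sub_maps, lab, spec,
                             seed = derive_seed(sseed, "noise"))
    recs[[s]] <- gr$rec
    labels[[s]] <- lab
    amps[[s]] <- gr$amplitude
    smaps[[s]] <- sub_maps
    params[[s]] <- list(duration_ms = spec$mean_duration_ms * dur_mult,
                        transition_matrix = tm, seed = sseed)
  }
  list(recordings = recs,
       ground_truth = list(maps = proto, subject_maps = smaps,
                           labels = labels, amplitude = amps,
                           params = params),
       spec = spec)
}

# Markov sequence with state-specific geometric mean durations (samples
# derived from dur_ms per state).
generate_state_sequence_perstate <- function(spec, n_samples, dur_ms, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  K <- spec$K_true
  p <- pmin(1, 1000 / (dur_ms * spec$srate))  # 1 / mean length in samples
  labels <- integer(n_samples)
  state <- sample.int(K, 1L)
  t <- 1L
  while (t <= n_samples) {
    len <- 1L + stats::rgeom(1L, p[state])
    end <- min(t + len - 1L, n_samples)
    labels[t:end] <- state
    t <- end + 1L
    if (K > 1L)
      state <- sample.int(K, 1L, prob = spec$transition_matrix[state, ])
  }
  labels
}

#' Generate a pair of binary volumes with a target global Dice overlap
#'
#' Builds two equal-size blob volumes by voxel-count construction so that
#' the global Dice coefficient `2|A^B| / (|A| + |B|)` equals
#' `overlap_fraction` up to rounding (well within 0.02 for the default
#' sizes).
#'
#' @param shape Integer length-3 grid dimensions.
#' @param n_blobs Number of spherical blobs forming volume A.
#' @param overlap_fraction Target global Dice in `[0, 1]`.
#' @param seed Integer seed.
#' @param voxel_size mm per axis.
#' @return A list of two [ms_volume()] objects `a` and `b`.
#' @export
generate_volume_pair <- function(shape = c(20L, 20L, 20L), n_blobs = 2L,
                                 overlap_fraction = 0.8, seed = 1L,
                                 voxel_size = c(1, 1, 1)) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  dims <- as.integer(shape)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                                  z = seq_len(dims[3L])))
  grid_a <- array(0L, dims)
  r <- max(2, round(min(dims) / 6))
  for (b in seq_len(n_blobs)) {
    ctr <- vapply(dims, function(d) stats::runif(1L, r + 1, d - r), numeric(1L))
    d2 <- rowSums(sweep(coords, 2L, ctr, "-")^2)
    grid_a[coords[d2 <= r^2, , drop = FALSE]] <- 1L
  }
  idx_a <- which(grid_a == 1L)
  nA <- length(idx_a)
  if (nA < 20L) stop("infeasible shape/blob combination: volume A too small")
  o <- round(overlap_fraction * nA)
  # keep o voxels of A (sorted by linear index: a contiguous chunk of the
  # blob) and add nA - o voxels from outside A, nearest to A's centroid
  keep <- idx_a[seq_len(o)]
  outside <- which(grid_a == 0L)
  if (length(outside) < nA - o)
    stop("infeasible shape/blob combination: not enough room for volume B")
  ctr_a <- colMeans(coords[idx_a, , drop = FALSE])
  d2_out <- rowSums(sweep(coords[outside, , drop = FALSE], 2L, ctr_a, "-")^2)
  add <- outside[order(d2_out)][seq_len(nA - o)]
  grid_b <- array(0L, dims)
  grid_b[c(keep, add)] <- 1L
  list(a = ms_volume(grid_a, voxel_size), b = ms_volume(grid_b, voxel_size))
}
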