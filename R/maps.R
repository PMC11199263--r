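#' Microstate topography set
#'
#' Holds K candidate or group microstate maps as a K x N matrix of
#' zero-mean, unit-norm channel vectors. Microstate maps are
#' sign-arbitrary; for reproducible serialization every map is oriented so
#' that its largest-magnitude channel is positive.
#'
#' @param maps K x N numeric matrix (states in rows). Each row is centred
#'   and scaled to unit norm; all-zero rows are an error.
#' @param state_names Optional state names (default "1".."K").
#' @param provenance Optional free-form list (level, duration, seed, ...).
#' @return An object of class `ms_maps`.
#' @export
ms_maps <- function(maps, state_names = NULL, provenance = list()) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) stop("need at least one map")
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) stop("maps must not be constant across channels")
  maps <- maps / nrm
  # sign convention: largest-|value| channel positive
  for (i in seq_len(nrow(maps))) {
    j <- which.max(abs(maps[i, ]))
    if (maps[i, j] < 0) maps[i, ] <- -maps[i, ]
  }
  if (is.null(state_names)) state_names <- as.character(seq_len(nrow(maps)))
  rownames(maps) <- state_names
  if (is.null(colnames(maps)))
    colnames(maps) <- paste0("ch", seq_len(ncol(maps)))
  structure(list(maps = maps, state_names = state_names,
                 provenance = provenance),
            class = "ms_maps")
}

#' @export
print.ms_maps <- function(x, ...) {
  cat("<ms_maps> ", nrow(x$maps), " maps x ", ncol(x$maps), " channels\n",
      sep = "")
  invisible(x)
}

#' Spatial correlation between topographies
#'
#' Pearson correlation across channels of two average-referenced
#' topographies, the standard similarity measure between scalp maps.
#' `abs_spatial_corr_matrix` returns all pairwise absolute correlations
#' between the rows of two map matrices (polarity ignored).
#'
#' @param u,v Numeric channel vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_corr <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  s <- sqrt(sum(u^2) * sum(v^2))
  if (s < 1e-300) return(0)
  sum(u * v) / s
}

#' @rdname spatial_corr
#' @param A,B Map matrices (rows = maps).
#' @export
abs_spatial_corr_matrix <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  A <- A / sqrt(rowSums(A^2)); B <- B / sqrt(rowSums(B^2))
  abs(tcrossprod(A, B))
}

# Unit-normalize zero-mean columns of a channels x samples matrix.
# Returns list(u = normalized matrix, norm = original column norms).
unit_columns <- function(X) {
  X <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(colSums(X^2))
  keep <- nrm > 1e-12
  U <- X
  U[, keep] <- sweep(X[, keep, drop = FALSE], 2L, nrm[keep], "/")
  list(u = U, norm = nrm, nonzero = keep)
}

#' Optimally pair two topography sets
#'
#' Finds the one-to-one assignment between the maps of two sets that
#' maximizes the total absolute spatial correlation. Exhaustive enumeration
#' is used for up to 8 maps, the Hungarian algorithm beyond that. When the
#' sets differ in size, surplus maps of the larger set are returned
#' unmatched and flagged.
#'
#' @param setA,setB [ms_maps()] objects (or bare map matrices).
#' @return A list with `pairs` (data.frame `a`, `b`, `abs_corr`),
#'   `total_corr`, and `unmatched` (indices of surplus maps in the larger
#'   set).
#' @export
match_maps <- function(setA, setB) {
  A <- if (inherits(setA, "ms_maps")) setA$maps else as.matrix(setA)
  B <- if (inherits(setB, "ms_maps")) setB$maps else as.matrix(setB)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("both sets must be non-empty")
  C <- abs_spatial_corr_matrix(A, B)
  swapped <- FALSE
  if (nrow(C) > ncol(C)) { C <- t(C); swapped <- TRUE }
  n <- nrow(C); m <- ncol(C)
  if (n <= 8L) {
    # exhaustive over assignments of the n rows into m columns
    best <- NULL; best_val <- -Inf
    cols <- utils::combn(m, n, simplify = FALSE)
    for (cc in cols) {
      perms <- permutations(n)
      for (p in seq_len(nrow(perms))) {
        idx <- cc[perms[p, ]]
        val <- sum(C[cbind(seq_len(n), idx)])
        if (val > best_val) { best_val <- val; best <- idx }
      }
    }
    assign_col <- best
  } else {
    assign_col <- hungarian_max(C)
  }
  ab <- cbind(seq_len(n), assign_col)
  if (swapped) ab <- ab[, c(2L, 1L), drop = FALSE]
  pairs <- data.frame(a = ab[, 1L], b = ab[, 2L],
                      abs_corr = C[cbind(seq_len(n), assign_col)])
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  nA <- nrow(A); nB <- nrow(B)
  unmatched <- if (nA > nB) setdiff(seq_len(nA), pairs$a)
               else setdiff(seq_len(nB), pairs$b)
  list(pairs = pairs, total_corr = sum(pairs$abs_corr),
       unmatched = unmatched,
       surplus_in = if (nA == nB) NA_character_ else if (nA > nB) "a" else "b")
}

# All permutations of 1..n as rows (n <= 8 in practice).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

# Hungarian algorithm (shortest augmenting path / Jonker-Volgenant style)
# maximizing the total score of a rectangular matrix with nrow <= ncol.
# Returns, for each row, the assigned column index.
hungarian_max <- function(S) {
  n <- nrow(S); m <- ncol(S)
  stopifnot(n <= m)
  cost <- max(S) - S  # minimize
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)  # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L  # column 0 sentinel is index 1 in R (columns shifted by 1)
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m) + 1L) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}
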