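#' Delay-coordinate embedding of a time series
#'
#' Reconstructs the shadow manifold of a series by lagged coordinates
#' (Takens' theorem): row `i` of the embedding is
#' `(x[t], x[t - tau], ..., x[t - (E-1) tau])` for its mapped time index `t`,
#' where `x` is the z-scored series in dynamical (oldest-to-youngest) order.
#' A [paleo_ts] (stored youngest-first by ascending age) is reversed
#' internally so the state flows forward in time; a plain numeric vector is
#' taken to be in forward time order already. z-scoring makes Euclidean
#' distances on the manifold scale-free.
#'
#' @param series a [paleo_ts] or numeric vector.
#' @param E embedding dimension (number of lag coordinates, `E >= 1`).
#' @param tau delay between coordinates in time steps (`tau >= 1`); with the
#'   coarse geological sampling used here one step is roughly 11 Myr and
#'   `tau = 1` is the default throughout the package.
#' @return An object of class `"delay_embedding"`: list with `vectors`
#'   (matrix, `n - (E-1)*tau` rows by `E` columns), `index_map` (row to
#'   time index of the lag-0 coordinate), `E`, `tau`, `n`, `name`.
#' @examples
#' e <- delay_embed(c(1, 2, 3, 4), E = 2, tau = 1)
#' nrow(e$vectors)  # 3
#' @export
delay_embed <- function(series, E, tau = 1L) {
  x <- dyn_values(series)
  n <- length(x)
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L) stop("'E' must be a positive integer", call. = FALSE)
  if (tau < 1L) stop("'tau' must be a positive integer", call. = FALSE)
  n_min <- (E - 1L) * tau + 2L
  if (n < n_min)
    stop(sprintf("series too short for E = %d, tau = %d: need at least %d points, have %d",
                 E, tau, n_min, n), call. = FALSE)
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  t_idx <- seq.int((E - 1L) * tau + 1L, n)
  vectors <- vapply(seq_len(E) - 1L,
                    function(j) z[t_idx - j * tau],
                    numeric(length(t_idx)))
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(t_idx))
  structure(list(vectors = vectors, index_map = t_idx,
                 E = E, tau = tau, n = n,
                 name = if (inherits(series, "paleo_ts")) series$name else "x"),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding> '%s': E = %d, tau = %d, %d vectors from %d samples\n",
              x$name, x$E, x$tau, nrow(x$vectors), x$n))
  invisible(x)
}

# Simplex weights for one query: distances d to the usable library points,
# nearest k kept, exponential kernel w_i = exp(-d_i / d_1) normalized to sum
# to one. Exact matches (d_1 = 0) get uniform weight among themselves.
# Ties in distance are broken by lower time index (deterministic).
.simplex_one <- function(d, pool_idx, k) {
  if (length(d) < k)
    stop(sprintf("need at least %d usable library neighbours, have %d",
                 k, length(d)), call. = FALSE)
  o <- order(d, pool_idx)[seq_len(k)]
  dn <- d[o]
  w <- if (dn[1L] == 0) as.numeric(dn == 0) else exp(-dn / dn[1L])
  list(idx = pool_idx[o], w = w / sum(w))
}

# One full simplex-projection pass over precomputed distances.
# D: full pairwise distance matrix among embedding rows; lib: library row
# indices; targets: target value per row; k: number of neighbours (E + 1).
# Queries are all rows; a query inside the library is excluded from its own
# neighbour set (leave-one-out).
.simplex_pass <- function(D, lib, targets, k) {
  nq <- nrow(D)
  preds <- numeric(nq)
  for (q in seq_len(nq)) {
    pool <- lib[lib != q]
    nb <- .simplex_one(D[q, pool], pool, k)
    preds[q] <- sum(nb$w * targets[nb$idx])
  }
  preds
}

# Row-stochastic simplex weight matrix for the full library (every row both
# query and library point, leave-one-out). Prediction for any target vector
# y is then W %*% y; used to evaluate many surrogate targets against a fixed
# manifold at no extra neighbour-search cost.
.simplex_weight_matrix <- function(D, k) {
  n <- nrow(D)
  W <- matrix(0, n, n)
  all_idx <- seq_len(n)
  for (q in all_idx) {
    pool <- all_idx[-q]
    nb <- .simplex_one(D[q, pool], pool, k)
    W[q, nb$idx] <- nb$w
  }
  W
}

# Pearson correlation that degrades gracefully: 0 when either side is
# constant (no linear skill rather than NA).
.safe_cor <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y))
  if (is.finite(r)) r else 0
}

#' Simplex-projection prediction
#'
#' Nearest-neighbour forecasting on an embedded manifold: for each query
#' point the `E + 1` nearest library points (Euclidean distance) are found
#' and the prediction is the weighted mean of their target values, with
#' weights `exp(-d_i / d_1)` normalized to sum to one (`d_1` the nearest
#' distance). If the nearest distance is zero, the exact-match neighbours
#' share uniform weight. Every prediction is a convex combination of
#' neighbour targets.
#'
#' @param library numeric matrix of embedded library points (rows) or a
#'   [delay_embed()] object.
#' @param targets numeric vector of target values aligned to the library
#'   rows.
#' @param query matrix of query points (same number of columns); default the
#'   library itself, in which case each query is excluded from its own
#'   neighbour search (leave-one-out).
#' @param exclude optional integer vector, one entry per query row: a library
#'   row index to exclude for that query (`NA` for none). Ignored when
#'   `query` is NULL (the default leave-one-out).
#' @return Numeric vector of predictions, one per query row.
#' @export
simplex_predict <- function(library, targets, query = NULL, exclude = NULL) {
  if (inherits(library, "delay_embedding")) library <- library$vectors
  library <- as.matrix(library)
  if (length(targets) != nrow(library))
    stop("'targets' must have one value per library row", call. = FALSE)
  k <- ncol(library) + 1L
  loo <- is.null(query)
  if (loo) {
    query <- library
    exclude <- seq_len(nrow(library))
  }
  query <- as.matrix(query)
  if (ncol(query) != ncol(library))
    stop("'query' and 'library' must have the same embedding dimension",
         call. = FALSE)
  nl <- nrow(library)
  preds <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    pool <- seq_len(nl)
    if (!is.null(exclude) && !is.na(exclude[i])) pool <- pool[pool != exclude[i]]
    d <- sqrt(colSums((t(library[pool, , drop = FALSE]) - query[i, ])^2))
    nb <- .simplex_one(d, pool, k)
    preds[i] <- sum(nb$w * targets[nb$idx])
  }
  preds
}

# Shared setup for cross mapping: embed A, index B onto the embedding rows.
.xmap_setup <- function(A, B, E, tau) {
  if (inherits(A, "paleo_ts") && inherits(B, "paleo_ts") && !same_grid(A, B))
    stop("'A' and 'B' are on different age grids; use align_series() first",
         call. = FALSE)
  emb <- delay_embed(A, E, tau)
  y <- dyn_values(B)
  if (length(y) != emb$n)
    stop("'A' and 'B' must have the same length", call. = FALSE)
  list(emb = emb,
       D = as.matrix(stats::dist(emb$vectors)),
       targets = y[emb$index_map],
       k = emb$E + 1L,
       label = paste(emb$name, "xmap",
                     if (inherits(B, "paleo_ts")) B$name else "y"))
}

# Draw library row indices for one replicate.
.draw_library <- function(n_rows, size, method) {
  if (method == "contiguous") {
    start <- sample.int(n_rows - size + 1L, 1L)
    seq.int(start, start + size - 1L)
  } else {
    sample.int(n_rows, size)
  }
}

#' Cross-map skill at a single library size
#'
#' Estimates series `B` from the shadow manifold of series `A` ("A xmap B"):
#' for each of `n_replicates` random libraries of `library_size` embedded
#' points of `A`, every valid time point is predicted by simplex projection
#' over that library (leave-one-out when the query is in the library), and
#' the skill is the Pearson correlation `rho` between estimates and observed
#' `B`. Substantial skill means information about `B` is encoded in `A`'s
#' manifold — evidence that B causally influences A.
#'
#' When `library_size` equals the number of embedding rows, sampling without
#' replacement always returns the full library, so all replicates are
#' identical; the skill is computed once and replicated.
#'
#' @param A,B [paleo_ts] objects on a shared grid (or numeric vectors in
#'   forward time order).
#' @param E,tau embedding parameters (see [delay_embed()]).
#' @param library_size number of library points, between `E + 2` and the
#'   embedding row count.
#' @param n_replicates random library draws (default 200).
#' @param seed RNG seed; identical seeds give identical results.
#' @param sample_method `"random"` (uniform without replacement, default) or
#'   `"contiguous"` (a random contiguous segment).
#' @return List with `direction`, `library_size`, `rho_mean`,
#'   `rho_replicates`, `E`, `tau`, `seed`.
#' @seealso [ccm()] for the full library-size ladder.
#' @export
cross_map <- function(A, B, E, tau = 1L, library_size,
                      n_replicates = 200L, seed = 1L,
                      sample_method = c("random", "contiguous")) {
  sample_method <- match.arg(sample_method)
  st <- .xmap_setup(A, B, E, tau)
  n_rows <- nrow(st$emb$vectors)
  library_size <- as.integer(library_size)
  if (library_size < st$k + 1L)
    stop(sprintf("'library_size' must be at least E + 2 = %d", st$k + 1L),
         call. = FALSE)
  if (library_size > n_rows)
    stop(sprintf("'library_size' (%d) exceeds the %d available embedding rows",
                 library_size, n_rows), call. = FALSE)
  rhos <- .xmap_replicates(st, library_size, n_replicates, seed, sample_method)
  list(direction = st$label, library_size = library_size,
       rho_mean = mean(rhos), rho_replicates = rhos,
       E = st$emb$E, tau = st$emb$tau, seed = seed)
}

# Replicate engine shared by cross_map() and ccm(). Uses the current RNG
# stream when seed is NULL (callers that manage their own stream).
.xmap_replicates <- function(st, library_size, n_replicates, seed,
                             sample_method) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_rows <- nrow(st$emb$vectors)
  if (library_size == n_rows) {
    # full library: every without-replacement draw is the same set
    preds <- .simplex_pass(st$D, seq_len(n_rows), st$targets, st$k)
    return(rep(.safe_cor(preds, st$targets), n_replicates))
  }
  vapply(seq_len(n_replicates), function(r) {
    lib <- .draw_library(n_rows, library_size, sample_method)
    preds <- .simplex_pass(st$D, lib, st$targets, st$k)
    .safe_cor(preds, st$targets)
  }, numeric(1))
}

#' Convergent cross mapping over a ladder of library sizes
#'
#' The central causal test of the package. Cross-map skill ("A xmap B",
#' see [cross_map()]) is evaluated at each library size of an increasing
#' ladder; convergence — skill rising with library size — is the defining
#' signature that the manifold of `A` encodes `B`, i.e. that B causally
#' influences A. Both the skill at the largest library (the summary statistic
#' used for significance testing, see [ccm_significance()]) and the maximum
#' mean skill over the ladder are reported.
#'
#' @inheritParams cross_map
#' @param library_sizes integer vector of library sizes, strictly increasing;
#'   default every size from `E + 2` up to the number of embedding rows.
#' @return An object of class `"ccm"`: list with `direction`,
#'   `library_sizes`, `rho_mean`, `rho_sd`, `rho_replicates` (matrix,
#'   replicates by sizes), `rho_terminal` (mean skill at the largest
#'   library), `rho_max` (max of `rho_mean`), `E`, `tau`, `n`,
#'   `n_replicates`, `seed`.
#' @examples
#' sys <- coupled_logistic(n = 45, seed = 7)     # truth: B -> A
#' fit <- ccm(sys$A, sys$B, E = 3, seed = 1)     # "A xmap B" detects B -> A
#' fit
#' @export
ccm <- function(A, B, E = 3L, tau = 1L, library_sizes = NULL,
                n_replicates = 200L, seed = 1L,
                sample_method = c("random", "contiguous")) {
  sample_method <- match.arg(sample_method)
  st <- .xmap_setup(A, B, E, tau)
  n_rows <- nrow(st$emb$vectors)
  if (is.null(library_sizes)) library_sizes <- seq.int(st$k + 1L, n_rows)
  library_sizes <- as.integer(library_sizes)
  if (is.unsorted(library_sizes, strictly = TRUE))
    stop("'library_sizes' must be strictly increasing", call. = FALSE)
  if (min(library_sizes) < st$k + 1L || max(library_sizes) > n_rows)
    stop(sprintf("'library_sizes' must lie in [%d, %d]", st$k + 1L, n_rows),
         call. = FALSE)
  set.seed(as.integer(seed))
  reps <- vapply(library_sizes, function(L) {
    .xmap_replicates(st, L, n_replicates, seed = NULL, sample_method)
  }, numeric(n_replicates))
  if (!is.matrix(reps)) reps <- matrix(reps, nrow = n_replicates)
  rho_mean <- colMeans(reps)
  structure(list(
    direction = st$label,
    library_sizes = library_sizes,
    rho_mean = rho_mean,
    rho_sd = apply(reps, 2L, stats::sd),
    rho_replicates = reps,
    rho_terminal = rho_mean[length(rho_mean)],
    rho_max = max(rho_mean),
    E = st$emb$E, tau = st$emb$tau, n = st$emb$n,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    call = match.call()
  ), class = "ccm")
}

#' @export
print.ccm <- function(x, ...) {
  cat("Convergent cross mapping\n")
  cat(sprintf("  direction : %s  (skill => the cross-mapped series drives the manifold series)\n",
              x$direction))
  cat(sprintf("  E = %d, tau = %d, n = %d, %d library replicates, seed %d\n",
              x$E, x$tau, x$n, x$n_replicates, x$seed))
  cat(sprintf("  library sizes %d..%d (%d rungs)\n",
              min(x$library_sizes), max(x$library_sizes),
              length(x$library_sizes)))
  cat(sprintf("  rho at largest library : %.4f\n", x$rho_terminal))
  cat(sprintf("  max mean rho           : %.4f\n", x$rho_max))
  invisible(x)
}

#' @export
summary.ccm <- function(object, ...) {
  df <- data.frame(library_size = object$library_sizes,
                   rho_mean = object$rho_mean,
                   rho_sd = object$rho_sd)
  structure(list(direction = object$direction, E = object$E,
                 tau = object$tau, table = df,
                 rho_terminal = object$rho_terminal,
                 rho_max = object$rho_max,
                 trend = stats::cor(object$library_sizes, object$rho_mean,
                                    method = "spearman")),
            class = "summary.ccm")
}

#' @export
print.summary.ccm <- function(x, ...) {
  cat(sprintf("CCM %s (E = %d, tau = %d)\n", x$direction, x$E, x$tau))
  cat(sprintf("  terminal rho %.4f, max rho %.4f, Spearman trend with library size %.3f\n",
              x$rho_terminal, x$rho_max, x$trend))
  print(utils::head(x$table, 5L))
  if (nrow(x$table) > 5L) cat(sprintf("  ... %d more rungs\n", nrow(x$table) - 5L))
  invisible(x)
}

#' @export
plot.ccm <- function(x, ...) {
  graphics::plot(x$library_sizes, x$rho_mean, type = "b", pch = 16, cex = 0.6,
                 ylim = range(0, x$rho_mean),
                 xlab = "library size L", ylab = expression(rho),
                 main = x$direction, ...)
  graphics::lines(x$library_sizes, x$rho_mean + x$rho_sd, lty = 3, col = "grey50")
  graphics::lines(x$library_sizes, pmax(-1, x$rho_mean - x$rho_sd), lty = 3,
                  col = "grey50")
  invisible(x)
}
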