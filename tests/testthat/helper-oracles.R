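# Brute-force simplex-projection oracle: explicit distance loops, repeated
# which.min extraction (ties resolve to the lowest index), and the weight
# formula applied directly. Deliberately independent of the package's
# vectorized implementation.
oracle_simplex <- function(library, targets, query, exclude = NULL) {
  k <- ncol(library) + 1L
  preds <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    ds <- rep(NA_real_, nrow(library))
    for (j in seq_len(nrow(library))) {
      if (!is.null(exclude) && !is.na(exclude[i]) && j == exclude[i]) next
      ds[j] <- sqrt(sum((query[i, ] - library[j, ])^2))
    }
    sel <- integer(0)
    dsel <- numeric(0)
    avail <- which(!is.na(ds))
    for (m in seq_len(k)) {
      best <- avail[which.min(ds[avail])]
      sel <- c(sel, best)
      dsel <- c(dsel, ds[best])
      avail <- setdiff(avail, best)
    }
    w <- if (dsel[1L] == 0) ifelse(dsel == 0, 1, 0) else exp(-dsel / dsel[1L])
    w <- w / sum(w)
    preds[i] <- sum(w * targets[sel])
  }
  preds
}

# Random simplex instance: library, targets, and external queries.
random_simplex_instance <- function() {
  E <- sample(1:4, 1L)
  n <- sample((E + 3L):50L, 1L)
  lib <- matrix(stats::rnorm(n * E), n, E)
  # occasionally duplicate a row to exercise the zero-distance rule
  if (stats::runif(1) < 0.3 && n > E + 3L) lib[2L, ] <- lib[1L, ]
  list(lib = lib, targets = stats::rnorm(n),
       query = matrix(stats::rnorm(3L * E), 3L, E))
}

# A short paleo grid shared by several fixtures.
demo_grid <- function(n = 10L) seq(0, 541, length.out = n)
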