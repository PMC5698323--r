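# Phase-randomized surrogate columns for a numeric vector using the current
# RNG stream. Amplitudes of the discrete Fourier transform are preserved
# exactly; phases of non-DC, non-Nyquist bins are uniform on [0, 2pi) with
# conjugate symmetry; for even length the Nyquist amplitude keeps a random
# sign. The original mean (DC) is preserved.
.ebisuzaki_matrix <- function(x, m) {
  n <- length(x)
  if (n < 4L) stop("surrogate generation needs at least 4 samples", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant series has no phase content to randomize", call. = FALSE)
  mu <- mean(x)
  F <- stats::fft(x - mu)
  amp <- Mod(F)
  even <- n %% 2L == 0L
  half <- if (even) n %/% 2L else (n + 1L) %/% 2L   # bins 2..half get phases
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    G <- complex(length.out = n)
    G[1L] <- F[1L]                                   # DC: zero after demean
    if (half >= 2L) {
      th <- stats::runif(half - 1L, 0, 2 * pi)
      ks <- 2L:half
      G[ks] <- amp[ks] * exp(1i * th)
      G[n + 2L - ks] <- Conj(G[ks])
    }
    if (even) {
      ny <- n %/% 2L + 1L
      G[ny] <- amp[ny] * sample(c(-1, 1), 1L)
    }
    out[, j] <- Re(stats::fft(G, inverse = TRUE)) / n + mu
  }
  out
}

#' Phase-randomization (Ebisuzaki) surrogate series
#'
#' Generates null series that share the original's full power spectrum —
#' hence, by the Wiener-Khinchin theorem, its autocorrelation structure —
#' but have independently randomized Fourier phases, destroying any
#' deterministic coupling to other series. The amplitude of every frequency
#' bin is preserved exactly and the mean (DC component) is unchanged; for
#' even length the Nyquist bin keeps its amplitude with a random sign.
#'
#' @param series a [paleo_ts] or numeric vector, length at least 4,
#'   non-constant.
#' @param n_surrogates how many surrogates to draw (default 1).
#' @param seed RNG seed.
#' @return For `n_surrogates = 1` a single surrogate in the same form as the
#'   input ([paleo_ts] on the same grid, or numeric vector); otherwise a
#'   matrix with one surrogate per column (rows in the input's storage
#'   order).
#' @export
ebisuzaki_surrogate <- function(series, n_surrogates = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  is_ts <- inherits(series, "paleo_ts")
  x <- if (is_ts) series$values else as.numeric(series)
  S <- .ebisuzaki_matrix(x, as.integer(n_surrogates))
  if (n_surrogates == 1L) {
    if (is_ts) paleo_ts(series$ages, S[, 1L],
                        name = paste0(series$name, " (surrogate)"),
                        units = series$units)
    else S[, 1L]
  } else S
}

#' Surrogate-based significance test for a CCM causal claim
#'
#' Tests whether the observed cross-map skill of "A xmap B" (evidence that B
#' drives A) exceeds what spectrum-preserving chance produces. The observed
#' statistic is the mean skill at the largest library (`statistic =
#' "terminal"`, the default) or the maximum mean skill over the ladder
#' (`"max"`). The null distribution replaces the putative *cause* — the
#' cross-mapped target series `B` — with [ebisuzaki_surrogate()] draws,
#' leaving the effect's manifold intact, which nulls exactly the information
#' CCM claims to detect; `surrogate = "effect"` or `"both"` randomize the
#' other side instead. The claim is significant when the observed skill
#' exceeds the empirical 95th percentile (linear interpolation between order
#' statistics) of the null skills.
#'
#' @inheritParams ccm
#' @param n_surrogates size of the null distribution (default 1000).
#' @param surrogate which series to phase-randomize under the null:
#'   `"cause"` (`B`; default), `"effect"` (`A`), or `"both"`.
#' @param statistic `"terminal"` (default) or `"max"` (recomputes the full
#'   ladder per surrogate; slow).
#' @param probs percentile defining the threshold (default 0.95).
#' @return An object of class `"ccm_test"`: list with `direction`,
#'   `observed_rho`, `null_rhos`, `percentile_95`, `significant`,
#'   `n_surrogates`, `seed`, `E`, `tau`, `statistic`, `surrogate`.
#' @examples
#' sys <- coupled_logistic(n = 45, seed = 7)  # truth: B -> A
#' ccm_significance(sys$A, sys$B, E = 3, n_surrogates = 100, seed = 1)
#' @export
ccm_significance <- function(A, B, E = 3L, tau = 1L,
                             n_surrogates = 1000L, seed = 1L,
                             surrogate = c("cause", "effect", "both"),
                             statistic = c("terminal", "max"),
                             library_sizes = NULL, n_replicates = 200L,
                             probs = 0.95) {
  surrogate <- match.arg(surrogate)
  statistic <- match.arg(statistic)
  n_surrogates <- as.integer(n_surrogates)
  a <- dyn_values(A)
  b <- dyn_values(B)
  if (inherits(A, "paleo_ts") && inherits(B, "paleo_ts") && !same_grid(A, B))
    stop("'A' and 'B' are on different age grids; use align_series() first",
         call. = FALSE)

  stat_fun <- function(av, bv) {
    if (statistic == "max") {
      fit <- ccm(av, bv, E = E, tau = tau, library_sizes = library_sizes,
                 n_replicates = n_replicates, seed = seed)
      fit$rho_max
    } else {
      st <- .xmap_setup(av, bv, E, tau)
      preds <- .simplex_pass(st$D, seq_len(nrow(st$emb$vectors)),
                             st$targets, st$k)
      .safe_cor(preds, st$targets)
    }
  }

  observed <- stat_fun(a, b)

  set.seed(as.integer(seed))
  surr_b <- if (surrogate %in% c("cause", "both"))
    .ebisuzaki_matrix(b, n_surrogates) else NULL
  surr_a <- if (surrogate %in% c("effect", "both"))
    .ebisuzaki_matrix(a, n_surrogates) else NULL

  null_rhos <- if (statistic == "terminal" && surrogate == "cause") {
    # the manifold of A is fixed under this null: reuse its simplex weights
    st <- .xmap_setup(a, b, E, tau)
    W <- .simplex_weight_matrix(st$D, st$k)
    vapply(seq_len(n_surrogates), function(j) {
      tg <- surr_b[st$emb$index_map, j]
      .safe_cor(as.numeric(W %*% tg), tg)
    }, numeric(1))
  } else {
    vapply(seq_len(n_surrogates), function(j) {
      av <- if (is.null(surr_a)) a else surr_a[, j]
      bv <- if (is.null(surr_b)) b else surr_b[, j]
      stat_fun(av, bv)
    }, numeric(1))
  }

  thr <- stats::quantile(null_rhos, probs = probs, type = 7, names = FALSE)
  structure(list(
    direction = paste(if (inherits(A, "paleo_ts")) A$name else "x", "xmap",
                      if (inherits(B, "paleo_ts")) B$name else "y"),
    observed_rho = observed,
    null_rhos = null_rhos,
    percentile_95 = thr,
    significant = observed > thr,
    n_surrogates = n_surrogates,
    seed = as.integer(seed),
    E = as.integer(E), tau = as.integer(tau),
    statistic = statistic, surrogate = surrogate
  ), class = "ccm_test")
}

#' @export
print.ccm_test <- function(x, ...) {
  cat("CCM surrogate significance test\n")
  cat(sprintf("  direction    : %s  (E = %d, tau = %d)\n", x$direction, x$E, x$tau))
  cat(sprintf("  null model   : Ebisuzaki phase randomization of the %s (%d draws)\n",
              switch(x$surrogate, cause = "putative cause",
                     effect = "effect series", both = "both series"),
              x$n_surrogates))
  cat(sprintf("  observed rho : %.4f   (%s statistic)\n", x$observed_rho,
              x$statistic))
  cat(sprintf("  95th pct null: %.4f\n", x$percentile_95))
  cat(sprintf("  verdict      : %s\n",
              if (x$significant) "SIGNIFICANT causal signal"
              else "not significant"))
  invisible(x)
}

#' @export
plot.ccm_test <- function(x, ...) {
  graphics::hist(x$null_rhos, breaks = 30, col = "grey85", border = "white",
                 xlim = range(c(x$null_rhos, x$observed_rho)),
                 xlab = expression(rho), main = x$direction, ...)
  graphics::abline(v = x$percentile_95, lty = 2)
  graphics::abline(v = x$observed_rho, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("95th pct of null", "observed"),
                   lty = c(2, 1), col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
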