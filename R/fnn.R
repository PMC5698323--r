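#' Optimal embedding dimension by the false-nearest-neighbour test
#'
#' Kennel-style diagnostic for choosing the embedding dimension `E`. For each
#' candidate `E`, every embedded point's nearest neighbour is found in the
#' `E`-dimensional reconstruction; the pair is a *false* neighbour if adding
#' the next lag coordinate separates it, i.e. if either
#' `|x[t + E*tau] - x[nn + E*tau]| / R_E > Rtol` (the loneliness criterion,
#' `R_E` the E-dimensional neighbour distance) or `R_{E+1} / R_A > Atol`
#' (the boundedness criterion, `R_{E+1}` the extended distance and `R_A` the
#' series standard deviation). The optimal `E` is the smallest with a false
#' fraction at most `threshold`; if none qualifies — typical for pure noise —
#' the `E` minimizing the fraction is returned with a warning.
#'
#' @param series a [paleo_ts] or numeric vector (forward time order).
#' @param tau delay in time steps (default 1).
#' @param E_max largest embedding dimension tried (default 6).
#' @param Rtol loneliness threshold (default 15).
#' @param Atol boundedness threshold (default 2).
#' @param threshold acceptable false-neighbour fraction (default 0.01).
#' @return An object of class `"fnn"`: list with `E` (chosen dimension),
#'   `fractions` (false-neighbour fraction per candidate `E`), `converged`
#'   (did any fraction reach `threshold`), plus the parameters.
#' @examples
#' x <- numeric(300); x[1] <- 0.3
#' for (t in 2:300) x[t] <- 3.8 * x[t - 1] * (1 - x[t - 1])
#' fnn_dimension(x)$E  # low: the logistic attractor is one-dimensional
#' @export
fnn_dimension <- function(series, tau = 1L, E_max = 6L,
                          Rtol = 15, Atol = 2, threshold = 0.01) {
  x <- dyn_values(series)
  n <- length(x)
  tau <- as.integer(tau); E_max <- as.integer(E_max)
  if (E_max < 1L) stop("'E_max' must be at least 1", call. = FALSE)
  if (n - E_max * tau < 2L)
    stop(sprintf("series too short for E_max = %d, tau = %d: need at least %d points, have %d",
                 E_max, tau, E_max * tau + 2L, n), call. = FALSE)
  R_A <- stats::sd(x)
  if (R_A == 0) stop("constant series has no neighbour structure", call. = FALSE)
  fractions <- numeric(E_max)
  for (E in seq_len(E_max)) {
    # forward-lag vectors v_t = (x[t], x[t+tau], ..., x[t+(E-1)tau]),
    # restricted to t for which the extension x[t + E*tau] exists
    t_idx <- seq_len(n - E * tau)
    V <- vapply(seq_len(E) - 1L, function(j) x[t_idx + j * tau],
                numeric(length(t_idx)))
    if (!is.matrix(V)) V <- matrix(V, nrow = length(t_idx))
    D <- as.matrix(stats::dist(V))
    diag(D) <- Inf
    nn <- apply(D, 1L, which.min)
    R_E <- D[cbind(seq_along(nn), nn)]
    extra <- abs(x[t_idx + E * tau] - x[nn + E * tau])
    lonely <- ifelse(R_E > 0, extra / R_E > Rtol, extra > 0)
    R_E1 <- sqrt(R_E^2 + extra^2)
    unbounded <- is.finite(R_E1) & (R_E1 / R_A > Atol)
    fractions[E] <- mean(lonely | unbounded)
  }
  ok <- which(fractions <= threshold)
  converged <- length(ok) > 0L
  E_opt <- if (converged) ok[1L] else {
    warning("false-neighbour fraction never fell below ", threshold,
            "; returning the minimizing E (series may be noise-dominated)",
            call. = FALSE)
    which.min(fractions)
  }
  structure(list(E = as.integer(E_opt), fractions = fractions,
                 converged = converged, tau = tau, E_max = E_max,
                 Rtol = Rtol, Atol = Atol, threshold = threshold),
            class = "fnn")
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("False-nearest-neighbour test (Rtol = %g, Atol = %g, tau = %d)\n",
              x$Rtol, x$Atol, x$tau))
  cat("  E        :", paste(seq_along(x$fractions)), "\n")
  cat("  FNN frac :", paste(sprintf("%.3f", x$fractions)), "\n")
  cat(sprintf("  optimal E = %d%s\n", x$E,
              if (x$converged) "" else "  (fallback: threshold never reached)"))
  invisible(x)
}
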