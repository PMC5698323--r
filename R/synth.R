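# Seed-deterministic AR(1) recursion with stationary initialization.
.ar1 <- function(n, phi, sd = 1) {
  e <- stats::rnorm(n, 0, sd)
  x <- numeric(n)
  x[1L] <- if (abs(phi) < 1) stats::rnorm(1L, 0, sd / sqrt(1 - phi^2)) else e[1L]
  for (t in seq_len(n)[-1L]) x[t] <- phi * x[t - 1L] + e[t]
  x
}

# Wrap a forward-time (oldest-first) value vector as a paleo_ts whose
# ascending-age storage reverses it, so dyn_values() recovers forward order.
.forward_ts <- function(values, ages_desc, name, units = "") {
  paleo_ts(rev(ages_desc), rev(values), name = name, units = units)
}

#' Unidirectionally coupled logistic maps: the CCM ground-truth benchmark
#'
#' Two chaotic logistic maps with tunable coupling,
#' `A(t+1) = A(t) * (r_a - r_a A(t) - beta_ab B(t))` and symmetrically for
#' `B`. A nonzero `beta_ab` means `B` enters `A`'s dynamics (truth: B drives
#' A); the defaults give the standard unidirectional benchmark with known
#' causal structure at the chaotic parameter regime, which cross mapping
#' ("A xmap B") should recover. A 300-step burn-in is discarded.
#'
#' @param r_a,r_b growth rates (chaotic regime defaults 3.8 and 3.7).
#' @param beta_ab coupling of `B` into `A`'s equation (default 0.3: B -> A).
#' @param beta_ba coupling of `A` into `B`'s equation (default 0: none).
#' @param n number of retained samples (default 45, the length of the
#'   Phanerozoic series the package analyses).
#' @param seed RNG seed for the random initial state.
#' @param burn_in discarded transient steps (default 300).
#' @return List with `A` and `B` ([paleo_ts], ages in abstract time steps,
#'   oldest sample at the largest age) and `truth`, a data frame of directed
#'   causal edges (`from`, `to`).
#' @examples
#' sys <- coupled_logistic(seed = 7)
#' sys$truth  # B -> A
#' @export
coupled_logistic <- function(r_a = 3.8, r_b = 3.7, beta_ab = 0.3,
                             beta_ba = 0, n = 45L, seed = 1L,
                             burn_in = 300L) {
  set.seed(as.integer(seed))
  n <- as.integer(n)
  total <- n + as.integer(burn_in)
  a <- numeric(total); b <- numeric(total)
  a[1L] <- stats::runif(1L, 0.2, 0.8)
  b[1L] <- stats::runif(1L, 0.2, 0.8)
  for (t in seq_len(total - 1L)) {
    a[t + 1L] <- a[t] * (r_a - r_a * a[t] - beta_ab * b[t])
    b[t + 1L] <- b[t] * (r_b - r_b * b[t] - beta_ba * a[t])
    if (!is.finite(a[t + 1L]) || !is.finite(b[t + 1L]) ||
        a[t + 1L] <= 0 || a[t + 1L] >= 1 || b[t + 1L] <= 0 || b[t + 1L] >= 1)
      stop("coupled logistic map left (0, 1): parameters outside the stable ",
           "chaotic regime", call. = FALSE)
  }
  keep <- seq.int(total - n + 1L, total)
  ages_desc <- seq.int(n - 1L, 0L)  # oldest first
  edges <- rbind(if (beta_ab > 0) data.frame(from = "B", to = "A"),
                 if (beta_ba > 0) data.frame(from = "A", to = "B"))
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  list(A = .forward_ts(a[keep], ages_desc, "A", "step units"),
       B = .forward_ts(b[keep], ages_desc, "B", "step units"),
       truth = edges)
}

#' Phanerozoic-like synthetic input bundle
#'
#' Emulates the statistical character of the study's inputs on a 45-point
#' grid spanning 541-0 Ma (about 12 Myr spacing): a geodynamic *driver* with
#' a secular linear trend, a superimposed ~130 Myr cycle and red (AR(1))
#' noise; a diversity-like *response* coupled to the driver at a one-step lag
#' with its own red noise; a positive total organic-C burial rate; and a C/S
#' ratio rising monotonically (plus small noise) from a low pre-land-plant
#' Early-Palaeozoic value to its modern maximum, with a late plateau. The
#' causal structure is known by construction: driver -> response when
#' `coupling > 0`, no edge at `coupling = 0`.
#'
#' @param n grid length (default 45; minimum 20).
#' @param span record length in Myr (default 541).
#' @param seed RNG seed.
#' @param coupling strength of the lagged driver effect on the response, in
#'   response units per standard deviation of the driver (default 1;
#'   response noise has sd 0.5, so the default signal-to-noise is 2:1).
#' @return List of [paleo_ts] — `driver`, `response`, `total_burial`,
#'   `cs_ratio` — plus `truth` (data frame of causal edges).
#' @export
phanerozoic_like <- function(n = 45L, span = 541, seed = 1L, coupling = 1) {
  n <- as.integer(n)
  if (n < 20L) stop("'n' must be at least 20", call. = FALSE)
  set.seed(as.integer(seed))
  ages_desc <- seq(span, 0, length.out = n)  # oldest first
  tt <- span - ages_desc                     # elapsed time since record start

  # driver: e.g. mean subducting-crust age (Myr), rising toward the present
  driver <- 40 + 20 * tt / span + 8 * sin(2 * pi * tt / 130) + .ar1(n, 0.5, 3)

  # response: diversity-like, positive, a lagged function of the z-scored
  # driver plus its own red noise; at coupling = 0 it is independent of the
  # driver by construction (any trend it shows then comes only through the
  # driver term)
  dz <- as.numeric(scale(driver))
  lag1 <- c(dz[1L], dz[-n])
  response <- 10 + coupling * lag1 + .ar1(n, 0.5, 0.5)
  response <- pmax(response, 0.1)

  # total burial: positive, Palaeozoic cyclicity + late rise
  burial <- 4 + 1.2 * sin(2 * pi * tt / 110) + 1.5 * (tt / span)^2 +
    .ar1(n, 0.5, 0.4)
  burial <- pmax(burial, 0.2)

  # C/S: smooth monotone logistic rise (low marine-dominated values early,
  # modern maximum) with plateau and small noise
  cs <- 0.5 + 2.3 / (1 + exp(-(tt - span * 0.45) / (span * 0.08))) +
    stats::rnorm(n, 0, 0.05)
  cs <- pmax(cs, 0.05)

  truth <- if (coupling > 0) data.frame(from = "driver", to = "response")
           else data.frame(from = character(), to = character())
  list(driver = .forward_ts(driver, ages_desc, "driver", "Myr"),
       response = .forward_ts(response, ages_desc, "response", "rel. diversity"),
       total_burial = .forward_ts(burial, ages_desc, "total_burial",
                                  "10^18 mol C/Myr"),
       cs_ratio = .forward_ts(cs, ages_desc, "cs_ratio", "C/S weight ratio"),
       truth = truth)
}

#' Independent AR(1) pair for type-I-error calibration
#'
#' Draws two mutually independent Gaussian AR(1) ("red noise") series with
#' identical spectra — the null configuration on which the surrogate-based
#' CCM test should reject at its nominal rate.
#'
#' @param phi AR(1) coefficient, `|phi| < 1` (default 0.5).
#' @param n series length (default 45).
#' @param seed RNG seed.
#' @param sd innovation standard deviation (default 1).
#' @return List with independent [paleo_ts] `A` and `B` (ages in abstract
#'   time steps).
#' @export
ar1_null <- function(phi = 0.5, n = 45L, seed = 1L, sd = 1) {
  if (abs(phi) >= 1) stop("'phi' must satisfy |phi| < 1", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  a <- .ar1(n, phi, sd)
  b <- .ar1(n, phi, sd)
  ages_desc <- seq.int(n - 1L, 0L)
  list(A = .forward_ts(a, ages_desc, "A", "z units"),
       B = .forward_ts(b, ages_desc, "B", "z units"))
}
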