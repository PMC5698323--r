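#' Terrestrial fraction of organic-carbon burial from the C/S ratio
#'
#' Maps the worldwide sedimentary organic-carbon to pyrite-sulfur weight ratio
#' (C/S) linearly onto the fraction of total organic-carbon burial occurring
#' in terrestrial (freshwater) settings. Low C/S characterizes marine euxinic
#' deposition (abundant sulfate reduction), so the minimum observed C/S is
#' taken to correspond to the minimum terrestrial share (zero); the maximum
#' C/S, reached when terrestrial plant-derived burial is strongest, maps to
#' `phi_max`, the assumed maximum terrestrial fraction.
#'
#' @param cs numeric vector of C/S ratios; values outside
#'   `[cs_min, cs_max]` are clipped into the interval.
#' @param cs_min,cs_max the C/S values anchored to zero and maximum
#'   terrestrial burial; `cs_min < cs_max` required.
#' @param phi_max maximum terrestrial fraction of total burial, in `[0, 1]`.
#'   The published procedure does not pin this constant; vary it in
#'   sensitivity runs.
#' @return Numeric vector of terrestrial fractions in `[0, phi_max]`.
#' @examples
#' terrestrial_fraction(c(0.5, 1.65, 2.8), 0.5, 2.8, phi_max = 0.6)
#' @export
terrestrial_fraction <- function(cs, cs_min, cs_max, phi_max) {
  if (!is.numeric(cs_min) || !is.numeric(cs_max) || cs_min >= cs_max)
    stop("'cs_min' must be strictly less than 'cs_max'", call. = FALSE)
  if (!is.numeric(phi_max) || phi_max < 0 || phi_max > 1)
    stop("'phi_max' must be a fraction in [0, 1]", call. = FALSE)
  cs <- pmin(pmax(cs, cs_min), cs_max)
  phi_max * (cs - cs_min) / (cs_max - cs_min)
}

#' Partition total organic-carbon burial into marine and terrestrial parts
#'
#' Splits the total organic-carbon burial rate at each time into a
#' terrestrial component, `terrestrial(t) = phi(cs(t)) * total(t)` with `phi`
#' the linear C/S map of [terrestrial_fraction()], and a marine component
#' `marine(t) = total(t) - terrestrial(t)`. Mass closure
#' (`marine + terrestrial == total`) holds exactly by construction, and both
#' components are non-negative. The marine component is the food-supply proxy
#' used to correct diversity.
#'
#' @param total [paleo_ts] of total organic-C burial rate (non-negative,
#'   model units such as 10^18 mol C/Myr).
#' @param cs [paleo_ts] of the C/S ratio on the same age grid as `total`
#'   (see [align_series()]).
#' @param phi_max maximum terrestrial fraction; default 0.5 (an assumption,
#'   see [terrestrial_fraction()]).
#' @param cs_min,cs_max anchor C/S values; default to the observed extremes
#'   of `cs`. C/S values outside the range (possible after interpolation when
#'   anchors are supplied) are clipped, with a message giving the count.
#' @return An object of class `"burial_partition"`: list with `grid` (ages),
#'   `total`, `cs`, `marine` and `terrestrial` ([paleo_ts] each), and
#'   `params`.
#' @examples
#' tot <- paleo_ts(c(0, 100), c(10, 10), "Corg burial", "10^18 mol C/Myr")
#' cs <- paleo_ts(c(0, 100), c(2.8, 0.5), "C/S", "")
#' partition_burial(tot, cs, phi_max = 0.5)
#' @export
partition_burial <- function(total, cs, phi_max = 0.5,
                             cs_min = NULL, cs_max = NULL) {
  stopifnot(inherits(total, "paleo_ts"), inherits(cs, "paleo_ts"))
  if (!same_grid(total, cs))
    stop("'total' and 'cs' are on different age grids; project them onto a ",
         "common base first with align_series()", call. = FALSE)
  if (any(total$values < 0))
    stop("total burial rate must be non-negative", call. = FALSE)
  if (is.null(cs_min)) cs_min <- min(cs$values)
  if (is.null(cs_max)) cs_max <- max(cs$values)
  n_clip <- sum(cs$values < cs_min | cs$values > cs_max)
  if (n_clip > 0L)
    message(n_clip, " C/S value(s) outside [", format(cs_min), ", ",
            format(cs_max), "] clipped")
  phi <- terrestrial_fraction(cs$values, cs_min, cs_max, phi_max)
  terr <- phi * total$values
  mar <- total$values - terr
  structure(list(
    grid = total$ages,
    total = total,
    cs = cs,
    terrestrial = paleo_ts(total$ages, terr, "terrestrial organic C burial",
                           total$units),
    marine = paleo_ts(total$ages, mar, "marine organic C burial", total$units),
    params = list(phi_max = phi_max, cs_min = cs_min, cs_max = cs_max,
                  n_clipped = n_clip)
  ), class = "burial_partition")
}

#' @export
print.burial_partition <- function(x, ...) {
  cat("Organic-carbon burial partition\n")
  cat(sprintf("  %d time points, %.6g-%.6g Ma\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  phi_max = %.3g, C/S anchors [%.4g, %.4g]\n",
              x$params$phi_max, x$params$cs_min, x$params$cs_max))
  cat(sprintf("  marine share of total burial: %.1f%% (mean), range %.1f-%.1f%%\n",
              100 * mean(x$marine$values / x$total$values),
              100 * min(x$marine$values / x$total$values),
              100 * max(x$marine$values / x$total$values)))
  invisible(x)
}

#' @export
plot.burial_partition <- function(x, ...) {
  rng <- range(0, x$total$values)
  graphics::plot(x$grid, x$total$values, type = "l", lty = 1,
                 xlim = rev(range(x$grid)), ylim = rng,
                 xlab = "Age (Ma)", ylab = x$total$units,
                 main = "Organic C burial partition", ...)
  graphics::lines(x$grid, x$marine$values, lty = 2, col = "steelblue")
  graphics::lines(x$grid, x$terrestrial$values, lty = 3, col = "sienna")
  graphics::legend("topleft", c("total", "marine", "terrestrial"),
                   lty = 1:3, col = c("black", "steelblue", "sienna"),
                   bty = "n")
  invisible(x)
}
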