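#' Correct diversity for changes in marine food supply
#'
#' Divides sampling-standardized diversity by the contemporaneous marine
#' organic-carbon burial rate, giving the number of lineages supported per
#' unit of marine food supply — i.e. the diversity signal that remains under
#' a hypothetical constant food supply. The corrected series is also returned
#' mean-normalized (mean exactly 1), the form used by the causal tests.
#'
#' @param diversity [paleo_ts] of diversity estimates (SQS or CR units).
#' @param marine_burial [paleo_ts] of marine organic-C burial rate on the
#'   same age grid; must be strictly positive everywhere.
#' @return An object of class `"corrected_diversity"`: list with `grid`,
#'   `raw`, `marine_burial`, `corrected` and `normalized` ([paleo_ts] each).
#' @examples
#' d <- paleo_ts(c(0, 100), c(4, 9), "SQS", "genera")
#' b <- paleo_ts(c(0, 100), c(2, 3), "marine burial", "rate")
#' correct_diversity(d, b)$corrected$values  # 2, 3
#' @export
correct_diversity <- function(diversity, marine_burial) {
  stopifnot(inherits(diversity, "paleo_ts"), inherits(marine_burial, "paleo_ts"))
  if (!same_grid(diversity, marine_burial))
    stop("'diversity' and 'marine_burial' are on different age grids; ",
         "use align_series() first", call. = FALSE)
  bad <- marine_burial$values <= 0
  if (any(bad))
    stop("marine burial rate must be positive; non-positive at ages (Ma): ",
         paste(format(marine_burial$ages[bad]), collapse = ", "),
         call. = FALSE)
  corr <- diversity$values / marine_burial$values
  corrected <- paleo_ts(diversity$ages, corr,
                        name = paste0("corrected ", diversity$name),
                        units = paste0(diversity$units, " per unit burial"))
  structure(list(
    grid = diversity$ages,
    raw = diversity,
    marine_burial = marine_burial,
    corrected = corrected,
    normalized = normalize_series(corrected, "mean")
  ), class = "corrected_diversity")
}

#' @export
print.corrected_diversity <- function(x, ...) {
  cat(sprintf("Resource-corrected diversity: %s / %s\n",
              x$raw$name, x$marine_burial$name))
  cat(sprintf("  %d time points, %.6g-%.6g Ma\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  corrected range: %.4g-%.4g %s\n",
              min(x$corrected$values), max(x$corrected$values),
              x$corrected$units))
  invisible(x)
}

#' @export
plot.corrected_diversity <- function(x, ...) {
  graphics::plot(x$grid, x$normalized$values, type = "l",
                 xlim = rev(range(x$grid)),
                 xlab = "Age (Ma)", ylab = "corrected diversity (mean = 1)",
                 main = x$corrected$name, ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Classify the per-capita food share of each time bin
#'
#' Mean-normalizes the uncorrected diversity and the marine burial-rate
#' series and compares them point by point against the 1:1 line. A bin where
#' normalized diversity exceeds normalized burial (`"above"`) is dominated by
#' lineages with a smaller per-capita share of food resources relative to the
#' normalization factor; `"below"` is the converse; `"on"` means equality
#' within `tol`.
#'
#' @param diversity,marine_burial [paleo_ts] objects on a shared age grid.
#' @param tol numeric tolerance on the normalized difference for the
#'   `"on"` label (default `1e-9`).
#' @return A data frame with columns `age_Ma`, `diversity_norm`,
#'   `burial_norm`, `class` (factor with levels below/on/above). Labels are
#'   invariant to rescaling either input.
#' @export
per_capita_class <- function(diversity, marine_burial, tol = 1e-9) {
  stopifnot(inherits(diversity, "paleo_ts"), inherits(marine_burial, "paleo_ts"))
  if (!same_grid(diversity, marine_burial))
    stop("'diversity' and 'marine_burial' are on different age grids; ",
         "use align_series() first", call. = FALSE)
  d <- normalize_series(diversity, "mean")$values
  b <- normalize_series(marine_burial, "mean")$values
  diff <- d - b
  cls <- ifelse(diff > tol, "above", ifelse(diff < -tol, "below", "on"))
  data.frame(age_Ma = diversity$ages,
             diversity_norm = d,
             burial_norm = b,
             class = factor(cls, levels = c("below", "on", "above")))
}
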