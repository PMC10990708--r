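#' Vesicle diameter from traced cross-sectional area
#'
#' Inverts the circle area formula: a vesicle whose traced outline encloses
#' area `A` (nm^2) has diameter `2 * sqrt(A / pi)` nm.
#'
#' @param area Numeric vector of traced areas (nm^2), all > 0.
#' @return Diameters in nm, same length as `area`.
#' @export
#' @examples
#' diameter_from_area(400 * pi) # 40 nm
diameter_from_area <- function(area) {
  if (!is.numeric(area) || length(area) == 0L || any(!is.finite(area)) ||
      any(area <= 0)) {
    abort("`area` must be positive and finite.",
          class = "svfusion_input_error")
  }
  2 * sqrt(area / pi)
}

#' Add diameters to a vesicle-area table
#'
#' @param areas Data frame with an `area_nm2` column (plus any metadata such
#'   as `vesicle_id`, `micrograph_id`, `pixel_size_nm`).
#' @return The input as a tibble with a `diameter_nm` column appended.
#' @export
add_diameters <- function(areas) {
  stopifnot(is.data.frame(areas), "area_nm2" %in% names(areas))
  as_tibble(areas) |>
    mutate(diameter_nm = diameter_from_area(.data$area_nm2))
}

#' Summarize a vesicle diameter distribution
#'
#' Arithmetic mean with SD and SEM, geometric mean (`exp(mean(log d))`, the
#' quantity dynamic light scattering instruments report) with its geometric
#' SD factor (`exp(sd(log d))`), and a half-open-bin histogram.
#'
#' @param values Numeric vector of diameters (nm), all > 0.
#' @param bin_width Histogram bin width (nm).
#' @return A `diameter_summary` list: `n`, `mean`, `sd`, `sem`,
#'   `geometric_mean`, `geometric_sd_factor`, and `histogram` (tibble:
#'   `bin_left`, `bin_right`, `count`).
#' @export
#' @examples
#' d <- rlnorm(500, log(40), 0.1)
#' summarize_diameters(d, bin_width = 2)
summarize_diameters <- function(values, bin_width = 2) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)) ||
      any(values <= 0)) {
    abort("diameters must be positive and finite (geometric mean undefined otherwise).",
          class = "svfusion_input_error")
  }
  check_positive_rate(bin_width, "bin_width")
  n <- length(values)
  s <- sd(values)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2L) edges <- c(lo, lo + bin_width)
  idx <- pmin(findInterval(values, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(
      n = n,
      mean = mean(values),
      sd = if (n > 1L) s else 0,
      sem = if (n > 1L) s / sqrt(n) else 0,
      geometric_mean = exp(mean(log(values))),
      geometric_sd_factor = if (n > 1L) exp(sd(log(values))) else 1,
      histogram = tibble(bin_left = edges[-length(edges)],
                         bin_right = edges[-1], count = as.integer(counts))
    ),
    class = "diameter_summary"
  )
}

#' @export
print.diameter_summary <- function(x, ...) {
  cat(sprintf(
    "<diameter_summary> n = %d; mean %.1f +/- %.2f nm (SEM; SD %.2f); geometric mean %.1f nm (GSD factor %.3f)\n",
    x$n, x$mean, x$sem, x$sd, x$geometric_mean, x$geometric_sd_factor))
  invisible(x)
}
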