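#' Histogram-based probability density with normal overlay
#'
#' Builds an equal-width histogram over `[min(values), max(values)]` with `p`
#' bins and normalizes each bin as Bin_i = k_i / (K * L), where k_i is the
#' count in bin i, K the total count and L the bin width, so that
#' sum(Bin_i * L) = 1. Values exactly at the right edge of the last bin fall
#' into it (closed last bin). A normal-density overlay with the sample mean
#' and sample standard deviation (n - 1 denominator) is evaluated on a
#' `g`-point equispaced grid spanning the data range.
#'
#' @param values numeric vector (length >= 2, not all equal).
#' @param p number of bins (default 20).
#' @param g number of overlay grid points (default 100).
#' @return A list of class `histogram_pdf`: `bin_edges` (length p + 1),
#'   `bin_values` (length p), `bin_width`, `counts`, and `overlay` with
#'   elements `mu`, `sigma`, `x`, `density`.
#' @examples
#' h <- histogram_pdf(rnorm(500, 180, 20))
#' sum(h$bin_values * h$bin_width)  # 1
#' @export
histogram_pdf <- function(values, p = 20L, g = 100L) {
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (length(values) < 2L) stop("need at least 2 values")
  p <- as.integer(p)
  if (p < 1L) stop("`p` must be >= 1")
  xmin <- min(values)
  xmax <- max(values)
  if (xmax == xmin) stop("all values identical: zero-width histogram")
  edges <- seq(xmin, xmax, length.out = p + 1L)
  L <- (xmax - xmin) / p
  # left-closed bins, last bin closed on both sides
  bin <- pmin(floor((values - xmin) / L) + 1L, p)
  counts <- tabulate(bin, nbins = p)
  K <- length(values)
  mu <- mean(values)
  sigma <- stats::sd(values)
  xg <- seq(xmin, xmax, length.out = as.integer(g))
  structure(
    list(
      bin_edges = edges,
      bin_values = counts / (K * L),
      bin_width = L,
      counts = counts,
      overlay = list(mu = mu, sigma = sigma, x = xg,
                     density = stats::dnorm(xg, mean = mu, sd = sigma))
    ),
    class = "histogram_pdf"
  )
}

#' @export
print.histogram_pdf <- function(x, ...) {
  cat(sprintf(
    "<histogram_pdf> %d bins of width %.4g over [%.4g, %.4g]; overlay N(%.4g, %.4g^2)\n",
    length(x$bin_values), x$bin_width, x$bin_edges[1],
    x$bin_edges[length(x$bin_edges)], x$overlay$mu, x$overlay$sigma
  ))
  invisible(x)
}

#' Percent growth between two survival counts
#'
#' 100 * (end - start) / start, reported to one decimal place.
#'
#' @param start_count plant count at the first survey (> 0).
#' @param end_count plant count at the last survey.
#' @return Percent growth, rounded to one decimal.
#' @examples
#' percent_growth(10, 51)  # 410.0
#' percent_growth(23, 36)  # 56.5
#' @export
percent_growth <- function(start_count, end_count) {
  if (start_count <= 0) stop("`start_count` must be positive")
  round(100 * (end_count - start_count) / start_count, 1)
}

#' Percent gap between two mean plant heights
#'
#' 100 * (mean_a - mean_b) / mean_b, reported to one decimal place; used to
#' compare final mean plant height between irrigation treatments.
#'
#' @param mean_a mean height of the first group (mm).
#' @param mean_b mean height of the reference group (mm, > 0).
#' @return Percent difference, rounded to one decimal.
#' @examples
#' height_gap_percent(212, 174)  # 21.8
#' @export
height_gap_percent <- function(mean_a, mean_b) {
  if (mean_b <= 0) stop("reference mean must be positive")
  round(100 * (mean_a - mean_b) / mean_b, 1)
}

#' Per-plot and per-group growth report
#'
#' Summarizes weekly surveys into per-plot time series of survival counts (and
#' mean heights when present), per-plot growth rates between the first and last
#' survey, and combined-group totals.
#'
#' @param surveys data frame with columns `date`, `field` and either
#'   `survival_count` or per-plant `height_mm` rows (or both); a `height_mm`
#'   column may also hold the plot-mean height when plants are not enumerated.
#' @param groups named list mapping group labels to character vectors of field
#'   ids, e.g. `list(group1 = c("A1", "A2"))`.
#' @return A list with `per_plot` (data frame: field, date, survival_count,
#'   mean_height_mm), `growth_rates` (field, start, end, percent), and
#'   `group_totals` (group, date, total_count, percent first to last).
#' @export
group_report <- function(surveys, groups = list()) {
  surveys <- as.data.frame(surveys)
  if (!all(c("date", "field") %in% names(surveys))) {
    stop("`surveys` needs `date` and `field` columns")
  }
  surveys$date <- as.Date(surveys$date)
  fields <- sort(unique(surveys$field))
  rows <- list()
  for (f in fields) {
    sub <- surveys[surveys$field == f, , drop = FALSE]
    for (d in sort(unique(sub$date))) {
      dd <- sub[sub$date == d, , drop = FALSE]
      cnt <- if ("survival_count" %in% names(dd)) dd$survival_count[1] else
        sum(!is.na(dd$height_mm))
      mh <- if ("height_mm" %in% names(dd)) mean(dd$height_mm, na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        field = f, date = as.Date(d, origin = "1970-01-01"),
        survival_count = cnt, mean_height_mm = mh
      )
    }
  }
  per_plot <- do.call(rbind, rows)
  gr <- list()
  for (f in fields) {
    sub <- per_plot[per_plot$field == f, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$date), , drop = FALSE]
    s <- sub$survival_count[1]
    e <- sub$survival_count[nrow(sub)]
    gr[[length(gr) + 1L]] <- data.frame(
      field = f, start = s, end = e,
      percent = if (s > 0) percent_growth(s, e) else NA_real_
    )
  }
  growth_rates <- do.call(rbind, gr)
  gt <- list()
  for (gname in names(groups)) {
    members <- groups[[gname]]
    sub <- per_plot[per_plot$field %in% members, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (d in sort(unique(sub$date))) {
      tot <- sum(sub$survival_count[sub$date == d])
      gt[[length(gt) + 1L]] <- data.frame(
        group = gname, date = as.Date(d, origin = "1970-01-01"), total_count = tot
      )
    }
  }
  group_totals <- if (length(gt)) do.call(rbind, gt) else NULL
  if (!is.null(group_totals)) {
    group_totals$percent <- NA_real_
    for (gname in unique(group_totals$group)) {
      i <- which(group_totals$group == gname)
      i <- i[order(group_totals$date[i])]
      s <- group_totals$total_count[i[1]]
      e <- group_totals$total_count[i[length(i)]]
      if (s > 0) group_totals$percent[i[length(i)]] <- percent_growth(s, e)
    }
  }
  list(per_plot = per_plot, growth_rates = growth_rates, group_totals = group_totals)
}
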