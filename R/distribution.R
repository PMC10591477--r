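#' Configuration for distribution summaries
#'
#' The kernel density estimate uses a Gaussian kernel with Scott's
#' bandwidth rule, h = sd(x) * n^(-1/5) (the default of the common plotting
#' stacks), evaluated on a uniform grid padded beyond the data range.
#'
#' @param bandwidth_rule Only `"scott"` is provided.
#' @param grid_points Grid size (>= 256; default 1024).
#' @param grid_padding Grid extension beyond the data range, in multiples
#'   of the bandwidth (default 3).
#' @return A `tn_stats_config`.
#' @export
stats_config <- function(bandwidth_rule = "scott", grid_points = 1024L,
                         grid_padding = 3) {
  bandwidth_rule <- match.arg(bandwidth_rule, "scott")
  stopifnot(grid_points >= 256L, grid_padding >= 0)
  structure(list(bandwidth_rule = bandwidth_rule,
                 grid_points = as.integer(grid_points),
                 grid_padding = grid_padding),
            class = "tn_stats_config")
}

scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Summarize a per-frame metric distribution
#'
#' Computes the summary statistics used to compare metric distributions
#' between states: sample mean and standard deviation (n-1 denominator),
#' the mode of a Gaussian-kernel density estimate (grid argmax), the full
#' width at half maximum (FWHM) of the density curve, and optionally the
#' fraction of samples above a threshold (e.g. the 110-degree open-state
#' threshold for the A/B helix angle).
#'
#' The FWHM is the distance between the outermost crossings of half the
#' peak density, located by linear interpolation on the grid; for bimodal
#' distributions it therefore spans the modes, and the per-mode widths are
#' additionally available via `fwhm_segments`.
#'
#' @param x Numeric samples (a `tn_series` is accepted), n >= 2.
#' @param config A `tn_stats_config`.
#' @param threshold Optional threshold for `fraction_above`.
#' @return A `tn_dist_summary`: list with `mean`, `sd`, `kde_mode`, `fwhm`,
#'   `fwhm_segments`, `fraction_above`, `threshold`, `n`, `bandwidth`,
#'   `degenerate` flag, and the density `grid`.
#' @export
summarize_distribution <- function(x, config = stats_config(),
                                   threshold = NULL) {
  if (inherits(x, "tn_series")) x <- x$value
  x <- as.numeric(x)
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  frac <- if (!is.null(threshold)) mean(x > threshold) else NA_real_

  if (s <= 1e-9 * max(1, abs(m))) {
    # (near-)constant series: mode is the constant, width undefined (flagged)
    out <- list(mean = m, sd = s, kde_mode = x[1], fwhm = NA_real_,
                fwhm_segments = NULL, fraction_above = frac,
                threshold = threshold, n = n, bandwidth = NA_real_,
                degenerate = TRUE, grid = NULL)
    return(structure(out, class = "tn_dist_summary"))
  }

  h <- scott_bandwidth(x)
  pad <- config$grid_padding * h
  den <- stats::density(x, bw = h, kernel = "gaussian",
                        n = config$grid_points,
                        from = min(x) - pad, to = max(x) + pad)
  peak <- which.max(den$y)
  half <- den$y[peak] / 2

  above <- den$y >= half
  cross <- function(i) {
    # linear interpolation of the half-max crossing between grid i and i+1
    den$x[i] + (half - den$y[i]) * (den$x[i + 1] - den$x[i]) /
      (den$y[i + 1] - den$y[i])
  }
  idx <- which(above)
  left <- if (idx[1] == 1L) den$x[1] else cross(idx[1] - 1L)
  rgt <- if (idx[length(idx)] == length(den$x))
    den$x[length(den$x)] else cross(idx[length(idx)])

  # contiguous above-half segments (per-mode widths for bimodal series)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- NULL
  for (q in which(runs$values)) {
    l <- if (starts[q] == 1L) den$x[1] else cross(starts[q] - 1L)
    r <- if (ends[q] == length(den$x)) den$x[length(den$x)] else cross(ends[q])
    seg <- rbind(seg, data.frame(left = l, right = r, width = r - l))
  }

  structure(
    list(mean = m, sd = s, kde_mode = den$x[peak], fwhm = rgt - left,
         fwhm_segments = seg, fraction_above = frac, threshold = threshold,
         n = n, bandwidth = h, degenerate = FALSE,
         grid = list(x = den$x, y = den$y)),
    class = "tn_dist_summary"
  )
}

#' @export
print.tn_dist_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Distribution summary (n = %d)\n", x$n))
  cat(sprintf("  mean (sd): %.*f (%.*f)\n", digits, x$mean, digits, x$sd))
  if (x$degenerate) {
    cat("  constant series: KDE mode equals the constant, FWHM undefined\n")
  } else {
    cat(sprintf("  KDE mode:  %.*f  (Scott bandwidth %.*f)\n",
                digits, x$kde_mode, digits, x$bandwidth))
    cat(sprintf("  FWHM:      %.*f", digits, x$fwhm))
    if (!is.null(x$fwhm_segments) && nrow(x$fwhm_segments) > 1) {
      cat(sprintf("  (%d modes: %s)", nrow(x$fwhm_segments),
                  paste(sprintf("%.*f", digits, x$fwhm_segments$width),
                        collapse = ", ")))
    }
    cat("\n")
  }
  if (!is.null(x$threshold)) {
    cat(sprintf("  fraction > %g: %.1f%%\n", x$threshold,
                100 * x$fraction_above))
  }
  invisible(x)
}

#' Plot a distribution summary
#'
#' Draws the kernel density estimate with the mode and the half-maximum
#' width marked.
#'
#' @param x A `tn_dist_summary`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tn_dist_summary <- function(x, ...) {
  if (x$degenerate) stop("constant series: nothing to plot")
  graphics::plot(x$grid$x, x$grid$y, type = "l", xlab = "value",
                 ylab = "density", ...)
  graphics::abline(v = x$kde_mode, lty = 2)
  half <- max(x$grid$y) / 2
  if (!is.null(x$fwhm_segments)) {
    graphics::segments(x$fwhm_segments$left, half, x$fwhm_segments$right,
                       half, col = 2)
  }
  invisible(x)
}

# round half away from zero (the convention of formatted percent changes)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohen's d effect size between two samples
#'
#' (mean_b - mean_a) / pooled standard deviation, with the classical pooled
#' standard deviation sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)).
#'
#' @param a,b Numeric sample vectors (n >= 2 each).
#' @return Signed effect size (positive when B has the larger mean).
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  cohens_d_stats(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b))
}

#' Cohen's d from summary statistics
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Per-state summary statistics.
#' @return Signed effect size.
#' @export
cohens_d_stats <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0) stop("zero pooled standard deviation: Cohen's d undefined")
  (mean_b - mean_a) / pooled
}

#' Compare two distribution summaries
#'
#' State-comparison arithmetic for a metric measured in two states A and B
#' (e.g. unphosphorylated vs phosphorylated): differences of mean, KDE mode
#' and FWHM (B minus A, always), FWHM percent change 100 * (B - A) / A, the
#' change in threshold fraction, and Cohen's d computed from the two
#' summaries' means, standard deviations and sample sizes. Raw values are
#' kept at full precision; the print method applies the conventional report
#' rounding (deltas to 2 decimals, percent changes half-away-from-zero to
#' integer percent).
#'
#' @param a,b `tn_dist_summary` objects for states A and B.
#' @return A `tn_comparison` list.
#' @export
state_delta <- function(a, b) {
  stopifnot(inherits(a, "tn_dist_summary"), inherits(b, "tn_dist_summary"))
  fwhm_pct <- if (!is.na(a$fwhm) && !is.na(b$fwhm) && a$fwhm != 0) {
    100 * (b$fwhm - a$fwhm) / a$fwhm
  } else NA_real_
  d <- tryCatch(cohens_d_stats(a$mean, a$sd, a$n, b$mean, b$sd, b$n),
                error = function(e) NA_real_)
  structure(
    list(delta_mean = b$mean - a$mean,
         delta_kde_mode = b$kde_mode - a$kde_mode,
         delta_fwhm = b$fwhm - a$fwhm,
         fwhm_percent_change = fwhm_pct,
         fwhm_percent_change_int = round_half_away(fwhm_pct),
         delta_fraction_above =
           if (!is.na(a$fraction_above) && !is.na(b$fraction_above))
             b$fraction_above - a$fraction_above else NA_real_,
         cohens_d = d,
         summary_a = a, summary_b = b),
    class = "tn_comparison"
  )
}

#' @export
print.tn_comparison <- function(x, ...) {
  cat("State comparison (B - A)\n")
  cat(sprintf("  delta mean:     %+.2f\n", x$delta_mean))
  cat(sprintf("  delta KDE mode: %+.2f\n", x$delta_kde_mode))
  if (!is.na(x$fwhm_percent_change)) {
    cat(sprintf("  FWHM change:    %+.2f (%+d%%)\n", x$delta_fwhm,
                as.integer(x$fwhm_percent_change_int)))
  }
  if (!is.na(x$delta_fraction_above)) {
    cat(sprintf("  delta fraction above threshold: %+.1f points\n",
                100 * x$delta_fraction_above))
  }
  if (!is.na(x$cohens_d)) cat(sprintf("  Cohen's d:      %+.3f\n", x$cohens_d))
  invisible(x)
}

#' Binding free-energy difference between two states
#'
#' Arithmetic on externally supplied binding free-energy summaries (e.g.
#' MMPBSA output): the change in mean binding free energy on going from
#' state A to state B, in kcal/mol. Inputs are either raw per-sample
#' vectors or `list(mean =, sd =, n =)` summaries.
#'
#' @param a,b Numeric vectors of binding free-energy samples, or summary
#'   lists with at least `mean`.
#' @return A `tn_energy_delta`: `mean_a`, `mean_b`, `ddg`
#'   (mean_b - mean_a), plus `cohens_d` when dispersions are available.
#' @export
energy_delta <- function(a, b) {
  as_sum <- function(x) {
    if (is.numeric(x)) {
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    } else {
      if (is.null(x$mean)) stop("energy summary must carry a mean")
      list(mean = x$mean,
           sd = if (!is.null(x$sd)) x$sd else NA_real_,
           n = if (!is.null(x$n)) x$n else NA_real_)
    }
  }
  sa <- as_sum(a); sb <- as_sum(b)
  d <- if (!is.na(sa$sd) && !is.na(sb$sd) && !is.na(sa$n) && !is.na(sb$n)) {
    tryCatch(cohens_d_stats(sa$mean, sa$sd, sa$n, sb$mean, sb$sd, sb$n),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(mean_a = sa$mean, mean_b = sb$mean,
                 ddg = sb$mean - sa$mean, cohens_d = d),
            class = "tn_energy_delta")
}

#' @export
print.tn_energy_delta <- function(x, ...) {
  cat(sprintf("Binding free-energy change: %.1f -> %.1f, ddG = %+.1f kcal/mol\n",
              x$mean_a, x$mean_b, x$ddg))
  invisible(x)
}
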