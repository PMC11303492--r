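## Small quantification formulas for the downstream cell assays: the two
## phospho/total protein percentages (electrochemiluminescence multiplex
## kit convention and western-blot densitometry convention), the fraction
## of cells oriented with flow, trapezoidal AUC for impedance/confluence
## time courses, and per-explant vessel-diameter summaries.

#' Percent phosphoprotein, multiplex (electrochemiluminescence) convention
#'
#' The phospho/total multiplex kit formula
#' \deqn{\%phospho = \frac{2 \cdot phospho}{phospho + total} \times 100,}
#' ranging over [0, 200] (100 when the two signals are equal).
#'
#' @param phospho,total non-negative signal intensities (assay units);
#'   vectorized, recycled to common length.
#' @return numeric vector of percentages in [0, 200].
#' @examples
#' pctPhosphoMultiplex(1, 3)   # 50
#' @export
pctPhosphoMultiplex <- function(phospho, total) {
  if (any(phospho < 0 | total < 0))
    stop("signals must be non-negative", call. = FALSE)
  den <- phospho + total
  if (any(den <= 0))
    stop("undefined: phospho + total signal must be > 0", call. = FALSE)
  200 * phospho / den
}

#' Percent phosphoprotein, western-blot densitometry convention
#'
#' \deqn{\%phospho = \frac{phospho}{total} \times 100.}
#'
#' @inheritParams pctPhosphoMultiplex
#' @return numeric vector of percentages (>= 0).
#' @examples
#' pctPhosphoWB(2, 8)   # 25
#' @export
pctPhosphoWB <- function(phospho, total) {
  if (any(phospho < 0 | total < 0))
    stop("signals must be non-negative", call. = FALSE)
  if (any(total <= 0))
    stop("undefined: total signal must be > 0", call. = FALSE)
  100 * phospho / total
}

#' Fold cell-axis angles into (-90, 90]
#'
#' A cell's long axis is undirected, so an angle and its value + 180° are
#' the same orientation; angles are reduced modulo 180° into (-90, 90],
#' with 0° the flow direction.
#'
#' @param angles numeric vector of angles in degrees.
#' @return folded angles in (-90, 90].
#' @examples
#' foldAngles(c(176, -90, 270))   # -4, 90, 90
#' @export
foldAngles <- function(angles) {
  f <- angles %% 180
  ifelse(f > 90, f - 180, f)
}

#' Fraction of cells oriented with the flow direction
#'
#' After axis folding ([foldAngles()]), the fraction of cells whose long
#' axis lies within \code{tolerance} degrees of the flow direction (0°) —
#' the "oriented in flow (0° ± 5°)" readout — plus a binned angle
#' distribution for orientation-profile curves.
#'
#' @param angles cell long-axis angles in degrees (flow = 0°); any real
#'   values, folded internally.
#' @param tolerance half-width of the oriented band in degrees (default 5).
#' @param binWidth histogram bin width in degrees (default 10); bins cover
#'   (-90, 90].
#' @return list with \code{fraction}, \code{n}, \code{folded} (the folded
#'   angles) and \code{histogram}
#'   (\code{data.frame(binStart, binEnd, count, freq)}).
#' @examples
#' orientationFraction(c(0, 1, 4, 6, 90))$fraction   # 3/5
#' @export
orientationFraction <- function(angles, tolerance = 5, binWidth = 10) {
  if (!length(angles))
    stop("invalid input: no angles supplied", call. = FALSE)
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  folded <- foldAngles(angles)
  frac <- mean(abs(folded) <= tolerance)
  breaks <- seq(-90, 90, by = binWidth)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  counts <- as.vector(table(cut(folded, breaks = breaks,
                                include.lowest = FALSE, right = TRUE)))
  ## cut() with right=TRUE leaves folded == -90 unbinned, but folding
  ## guarantees (-90, 90]
  hist <- data.frame(binStart = breaks[-length(breaks)],
                     binEnd = breaks[-1L], count = counts,
                     freq = counts / length(folded))
  list(fraction = frac, n = length(angles), folded = folded,
       histogram = hist)
}

#' Trapezoidal area under a time-course curve
#'
#' AUC of an impedance (migration) or percent-confluence (proliferation)
#' time course by the trapezoidal rule over the full time range.
#'
#' @param time strictly increasing numeric vector (hours).
#' @param value numeric vector of the same length (>= 2 points).
#' @return single numeric, the integral.
#' @examples
#' aucTrapezoid(c(0, 1, 2), c(0, 2, 0))   # 2
#' @export
aucTrapezoid <- function(time, value) {
  if (length(time) != length(value) || length(time) < 2L)
    stop("'time' and 'value' must have equal length >= 2", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("invalid input: 'time' must be strictly increasing", call. = FALSE)
  pracma::trapz(time, value)
}

#' Per-explant vessel-diameter summary
#'
#' Summarises a table of traced vessel segments: per explant (the unit of
#' analysis), the mean and median segment diameter; plus a pooled binned
#' diameter distribution across all segments.
#'
#' @param segments \code{data.frame} of traced segments with columns \code{explant_id},
#'   \code{mean_diameter} (µm, > 0) and optionally \code{segment_id}.
#' @param binWidth pooled-histogram bin width in µm (default 5).
#' @return list with \code{perExplant}
#'   (\code{data.frame(explant_id, n_segments, mean_diameter,
#'   median_diameter)}, ordered by explant id) and \code{pooled}
#'   (\code{data.frame(binStart, binEnd, count, freq)}).
#' @examples
#' tab <- data.frame(explant_id = "e1", mean_diameter = c(10, 20, 30))
#' diameterSummary(tab)$perExplant
#' @export
diameterSummary <- function(segments, binWidth = 5) {
  if (!all(c("explant_id", "mean_diameter") %in% names(segments)))
    stop("'segments' needs columns explant_id and mean_diameter",
         call. = FALSE)
  if (nrow(segments) < 1L) stop("empty segment table", call. = FALSE)
  d <- segments$mean_diameter
  if (any(!is.finite(d) | d <= 0))
    stop("invalid input: diameters must be positive", call. = FALSE)
  sp <- split(d, as.character(segments$explant_id))
  sp <- sp[order(names(sp))]
  perExplant <- data.frame(
    explant_id = names(sp),
    n_segments = vapply(sp, length, 1L),
    mean_diameter = vapply(sp, mean, 1),
    median_diameter = vapply(sp, stats::median, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  top <- binWidth * ceiling(max(d) / binWidth)
  breaks <- seq(0, top, by = binWidth)
  counts <- as.vector(table(cut(d, breaks = breaks, right = TRUE)))
  pooled <- data.frame(binStart = breaks[-length(breaks)],
                       binEnd = breaks[-1L], count = counts,
                       freq = counts / length(d))
  list(perExplant = perExplant, pooled = pooled)
}
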