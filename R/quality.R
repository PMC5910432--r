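#' Construct an electropherogram trace
#'
#' A capillary-electrophoresis trace of total RNA: fluorescence (arbitrary
#' units) against fragment size in nucleotides. The analysis window excludes
#' the lower-marker region of the chip; all quality metrics integrate only
#' inside the window.
#'
#' @param size_nt Strictly increasing fragment sizes in nucleotides.
#' @param fluorescence Non-negative fluorescence values, one per size.
#' @param window Length-2 numeric, the analysis window in nt. The default
#'   lower bound of 25 nt clips the marker peak of small-RNA chips.
#' @return A tibble of class `electropherogram` with columns `size_nt` and
#'   `fluorescence` and the window stored as an attribute.
#' @examples
#' tr <- electropherogram(seq(25, 1000, 5), dgamma(seq(25, 1000, 5), 2, scale = 200))
#' dv200(tr)
#' @export
electropherogram <- function(size_nt, fluorescence, window = c(25, Inf)) {
  if (length(size_nt) != length(fluorescence)) {
    stop_invalid("size_nt and fluorescence must have equal length.")
  }
  if (any(!is.finite(size_nt)) || any(diff(size_nt) <= 0)) {
    stop_invalid("Fragment sizes must be finite and strictly increasing.")
  }
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0)) {
    stop_invalid("Fluorescence must be finite and non-negative.")
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_invalid("`window` must be (min, max) with min < max.")
  }
  structure(
    tibble(size_nt = as.numeric(size_nt), fluorescence = as.numeric(fluorescence)),
    window = as.numeric(window),
    class = c("electropherogram", "tbl_df", "tbl", "data.frame")
  )
}

as_electropherogram <- function(trace, window = NULL) {
  if (inherits(trace, "electropherogram") && is.null(window)) return(trace)
  win <- window %||% attr(trace, "window") %||% c(25, Inf)
  if (!all(c("size_nt", "fluorescence") %in% names(trace))) {
    stop_invalid("A trace needs columns size_nt and fluorescence.")
  }
  electropherogram(trace$size_nt, trace$fluorescence, window = win)
}

trace_window <- function(trace) attr(trace, "window") %||% c(25, Inf)

# Sum of trapezoid areas over consecutive points.
trapezoid_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' DV200: percentage of RNA fragments longer than 200 nucleotides
#'
#' The standard quality score for fragmented (e.g. FFPE-derived) RNA, for
#' which ribosomal-peak-based integrity numbers are uninformative: the
#' fraction of the trace's integrated fluorescence that lies above 200 nt,
#' in percent. Integration is trapezoidal within the analysis window; when
#' the 200 nt boundary falls between grid points, the crossing trapezoid is
#' split by linear interpolation so the score does not depend on grid
#' placement.
#'
#' @param trace An [electropherogram()] or a data frame with columns
#'   `size_nt` and `fluorescence`.
#' @param threshold Fragment-size boundary in nt (200 for DV200).
#' @param window Optional analysis window overriding the trace's own.
#' @param baseline Constant baseline to subtract before integration
#'   (negative results are clipped to zero). Traces are normally exported
#'   baseline-corrected, so the default is 0.
#' @return DV200 in percent, a single number in \[0, 100\].
#' @export
dv200 <- function(trace, threshold = 200, window = NULL, baseline = 0) {
  tr <- as_electropherogram(trace, window)
  win <- trace_window(tr)

  keep <- tr$size_nt >= win[1] & tr$size_nt <= win[2]
  x <- tr$size_nt[keep]
  y <- pmax(tr$fluorescence[keep] - baseline, 0)
  if (length(x) < 2L) {
    stop_invalid("Fewer than 2 trace points inside the analysis window.")
  }

  # Insert an interpolated point at the threshold so trapezoids split there.
  if (threshold > min(x) && threshold < max(x) && !any(x == threshold)) {
    y_at <- stats::approx(x, y, xout = threshold)$y
    ord <- order(c(x, threshold))
    y <- c(y, y_at)[ord]
    x <- c(x, threshold)[ord]
  }

  total <- trapezoid_area(x, y)
  if (total <= 0) {
    stop_undefined("Zero total fluorescence inside the analysis window; DV200 undefined.")
  }
  above_idx <- x >= threshold
  above <- trapezoid_area(x[above_idx], y[above_idx])
  100 * above / total
}

#' Detect a putative cross-link peak in the high-molecular-weight region
#'
#' Incompletely de-cross-linked nucleic acids in FFPE extracts show up as a
#' well-delimited peak after the fragment plateau, typically around
#' 3,000-4,000 nt. A local maximum inside the search window is reported when
#' its height exceeds `prominence_factor` times the median fluorescence of
#' the trace outside the search window (the plateau level).
#'
#' @inheritParams dv200
#' @param search_window Size range (nt) scanned for the peak.
#' @param prominence_factor Required height relative to the plateau median.
#' @return A one-row tibble (`center_nt`, `height`, `prominence`) when a
#'   peak is found, otherwise a zero-row tibble of the same shape.
#' @export
detect_high_mw_peak <- function(trace, search_window = c(2500, 5000),
                                prominence_factor = 2, window = NULL) {
  tr <- as_electropherogram(trace, window)
  win <- trace_window(tr)
  if (search_window[1] < win[1] || search_window[1] > max(tr$size_nt)) {
    stop_invalid("Search window lies outside the trace's analysis window.")
  }

  keep <- tr$size_nt >= win[1] & tr$size_nt <= win[2]
  x <- tr$size_nt[keep]
  y <- tr$fluorescence[keep]

  inside <- x >= search_window[1] & x <= search_window[2]
  outside <- !inside
  if (sum(inside) == 0L || sum(outside) == 0L) {
    stop_invalid("Search window leaves no points inside or outside it.")
  }
  plateau <- median(y[outside])

  none <- tibble(center_nt = numeric(), height = numeric(), prominence = numeric())

  # Strict local maxima: higher than both neighbours.
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max & inside)
  if (length(cand) == 0L) return(none)

  best <- cand[which.max(y[cand])]
  if (plateau > 0 && y[best] <= prominence_factor * plateau) return(none)
  if (plateau <= 0 && y[best] <= 0) return(none)

  tibble(
    center_nt = x[best],
    height = y[best],
    prominence = if (plateau > 0) y[best] / plateau else Inf
  )
}

#' Classify RNA quality from a DV200 value
#'
#' Applies the published input-quality scale for fragmented RNA: DV200 above
#' 70% is high quality, 50-70% medium (usable with increased input), and
#' below 30% too degraded for profiling. The 30-50% range is not assigned a
#' category by that scale, so it is reported as `"unassigned"` rather than
#' silently folded into a neighbouring class.
#'
#' @param dv200 Numeric vector of DV200 percentages in \[0, 100\].
#' @return Factor with levels `low < unassigned < medium < high`.
#' @examples
#' classify_quality(c(85, 60, 40, 20))
#' @export
classify_quality <- function(dv200) {
  if (any(!is.finite(dv200)) || any(dv200 < 0 | dv200 > 100)) {
    stop_invalid("DV200 values must lie in [0, 100].")
  }
  out <- ifelse(dv200 > 70, "high",
         ifelse(dv200 >= 50, "medium",
         ifelse(dv200 >= 30, "unassigned", "low")))
  factor(out, levels = c("low", "unassigned", "medium", "high"), ordered = TRUE)
}

#' Full quality assessment of one trace
#'
#' Runs [dv200()], [classify_quality()] and [detect_high_mw_peak()] and
#' returns one tidy row, the JSON-ready quality record of a sample.
#'
#' @inheritParams detect_high_mw_peak
#' @return One-row tibble: `dv200`, `category`, `crosslink_peak` (logical),
#'   `peak_center_nt`, `peak_prominence` (NA when absent).
#' @export
assess_rna_quality <- function(trace, search_window = c(2500, 5000),
                               prominence_factor = 2, window = NULL) {
  tr <- as_electropherogram(trace, window)
  score <- dv200(tr)
  peak <- detect_high_mw_peak(tr, search_window = search_window,
                              prominence_factor = prominence_factor)
  tibble(
    dv200 = score,
    category = as.character(classify_quality(score)),
    crosslink_peak = nrow(peak) == 1L,
    peak_center_nt = if (nrow(peak)) peak$center_nt else NA_real_,
    peak_prominence = if (nrow(peak)) peak$prominence else NA_real_
  )
}
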