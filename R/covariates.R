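#' Candidate spatial scales
#'
#' Candidate circular moving-window radii used for scale selection: 2.5, 5 and
#' 10 km for population (lek) analyses, and 75, 167, 260, 370, 439 and 1451 m
#' for life-stage (nest/brood/adult) analyses. The same life-stage set supplies
#' the decay constants alpha of the exponential proximity function. 1439 m is
#' accepted as an alias for the largest life-stage radius.
#'
#' @param kind `"population"` or `"life_stage"`.
#' @return Numeric vector of radii in metres.
#' @export
candidate_scales <- function(kind = c("population", "life_stage")) {
  kind <- match.arg(kind)
  switch(kind,
    population = c(2500, 5000, 10000),
    life_stage = c(75, 167, 260, 370, 439, 1451))
}

#' Circular moving-window mean over a gridded field
#'
#' Mean of all cells whose centres lie within Euclidean distance `radius` of
#' the focal cell's centre. Cells outside the grid are excluded from both
#' numerator and denominator (no padding).
#'
#' @param grid Numeric matrix (rows = y, columns = x).
#' @param center Integer vector `c(row, col)` of the focal cell.
#' @param radius Window radius, in the same units as `cell_size`.
#' @param cell_size Grid cell edge length (default 1).
#' @return The windowed mean (scalar).
#' @export
moving_window_mean <- function(grid, center, radius, cell_size = 1) {
  stopifnot(is.matrix(grid), length(center) == 2L)
  i0 <- center[1]; j0 <- center[2]
  if (i0 < 1 || i0 > nrow(grid) || j0 < 1 || j0 > ncol(grid)) {
    stop("center must lie inside the grid")
  }
  if (radius < 0) stop("radius must be non-negative")
  # cell centres are spaced cell_size apart; work in cell units
  r_cells <- radius / cell_size
  di <- outer(seq_len(nrow(grid)) - i0, rep(1, ncol(grid)))
  dj <- outer(rep(1, nrow(grid)), seq_len(ncol(grid)) - j0)
  inside <- (di^2 + dj^2) <= r_cells^2 + 1e-12
  inside <- inside & !is.na(grid)
  if (!any(inside)) stop("moving window covers zero cells")
  mean(grid[inside])
}

#' Exponential distance decay
#'
#' `exp(-d / alpha)`, a proximity index in (0, 1] that equals 1 at distance 0
#' and decays with e-folding length `alpha`.
#'
#' @param d Distance(s), >= 0.
#' @param alpha Decay constant, > 0 (same units as `d`).
#' @return Numeric vector of proximity values in (0, 1].
#' @export
distance_decay <- function(d, alpha) {
  if (any(d < 0)) stop("distance d must be non-negative")
  if (alpha <= 0) stop("alpha must be positive")
  exp(-d / alpha)
}

#' Named climate lag windows
#'
#' Definitions of the seasonal and annual averaging windows applied to climate
#' series, resolved relative to a response year t (the spring lek count of
#' year t, or a survival interval in year t):
#' \describe{
#'   \item{previous_calendar_year}{14 Mar of t-1 through 14 Mar of t.}
#'   \item{water_year}{1 Oct of t-2 through 30 Sep of t-1 (the hydrologic
#'     year preceding the count).}
#'   \item{growing_season}{1 Apr - 31 Oct of t-1.}
#'   \item{spring}{1 Mar - 31 May of t-1 (population lag).}
#'   \item{summer}{1 Jun - 31 Aug of t-1.}
#'   \item{fall}{1 Sep - 30 Nov of t-1.}
#'   \item{winter}{1 Dec of t-1 through end of Feb of t (29 Feb in leap
#'     years).}
#'   \item{spring_mar_may}{1 Mar - 31 May of t (concurrent spring, survival
#'     models).}
#' }
#'
#' @return Named list of window definitions (month-day anchors plus year
#'   offsets for start and end).
#' @export
lag_windows <- function() {
  w <- function(sm, sd_, so, em, ed, eo) {
    list(start_month = sm, start_day = sd_, start_offset = so,
         end_month = em, end_day = ed, end_offset = eo)
  }
  list(
    previous_calendar_year = w(3, 14, -1, 3, 14, 0),
    water_year             = w(10, 1, -2, 9, 30, -1),
    growing_season         = w(4, 1, -1, 10, 31, -1),
    spring                 = w(3, 1, -1, 5, 31, -1),
    summer                 = w(6, 1, -1, 8, 31, -1),
    fall                   = w(9, 1, -1, 11, 30, -1),
    winter                 = w(12, 1, -1, 2, 28, 0),
    spring_mar_may         = w(3, 1, 0, 5, 31, 0)
  )
}

#' Resolve a lag window to absolute dates
#'
#' @param window A window name from [lag_windows()], or a window definition
#'   list of the same shape.
#' @param response_year The response calendar year t.
#' @return A list with `start` and `end` [Date]s (both inclusive). The winter
#'   window ends 29 Feb when the end year is a leap year.
#' @export
resolve_lag_window <- function(window, response_year) {
  if (is.character(window)) {
    defs <- lag_windows()
    if (!window %in% names(defs)) {
      stop("unknown lag window '", window, "'; see lag_windows()")
    }
    window <- defs[[window]]
  }
  sy <- response_year + window$start_offset
  ey <- response_year + window$end_offset
  ed <- window$end_day
  if (window$end_month == 2 && ed >= 28 && is_leap_year(ey)) ed <- 29
  list(start = as.Date(sprintf("%04d-%02d-%02d", sy, window$start_month, window$start_day)),
       end = as.Date(sprintf("%04d-%02d-%02d", ey, window$end_month, ed)))
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Resolve a concurrent (survival-model) window around an exposure interval
#'
#' Survival models use short-lag weather windows tied to the exposure
#' interval itself rather than to a response year: the interval's own
#' calendar month (`"current_month"`), the month before it
#' (`"previous_month"`), or the enclosing spring (`"spring_mar_may"`, 1 Mar -
#' 31 May of the interval's year). The interval is located by its midpoint
#' date (whether such windows anchor on the interval's start or midpoint is
#' ambiguous in field usage; the midpoint is the documented convention here).
#'
#' @param start,end Interval start and end [Date]s (inclusive).
#' @param window `"current_month"`, `"previous_month"`, or
#'   `"spring_mar_may"`.
#' @return A list with `start` and `end` dates of the resolved window.
#' @export
resolve_concurrent_window <- function(start, end,
                                      window = c("current_month",
                                                 "previous_month",
                                                 "spring_mar_may")) {
  window <- match.arg(window)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("interval end precedes start")
  mid <- start + floor(as.numeric(end - start) / 2)
  y <- as.integer(format(mid, "%Y"))
  m <- as.integer(format(mid, "%m"))
  if (window == "spring_mar_may") {
    return(list(start = as.Date(sprintf("%04d-03-01", y)),
                end = as.Date(sprintf("%04d-05-31", y))))
  }
  if (window == "previous_month") {
    m <- m - 1L
    if (m == 0L) { m <- 12L; y <- y - 1L }
  }
  first <- as.Date(sprintf("%04d-%02d-01", y, m))
  nxt <- if (m == 12L) as.Date(sprintf("%04d-01-01", y + 1L)) else
    as.Date(sprintf("%04d-%02d-01", y, m + 1L))
  list(start = first, end = nxt - 1)
}

#' Aggregate a climate series over a lag window
#'
#' Filters a dated climate series to the resolved window (endpoints inclusive)
#' and aggregates. The default is the arithmetic mean; `fun = "sum"` gives
#' cumulative totals (the natural mode for precipitation), and `"min"`/`"max"`
#' give monthly extrema of temperature series.
#'
#' @param series A data.frame with columns `date` (coercible to [Date]) and
#'   `value`. Record order is irrelevant.
#' @param window Window name or definition (see [resolve_lag_window()]).
#' @param response_year Response calendar year t.
#' @param fun Aggregation: `"mean"` (default), `"sum"`, `"min"`, `"max"`.
#' @return Scalar aggregate, or `NA` (with a warning) when the window contains
#'   no data.
#' @export
aggregate_lag_window <- function(series, window, response_year,
                                 fun = c("mean", "sum", "min", "max")) {
  fun <- match.arg(fun)
  stopifnot(all(c("date", "value") %in% names(series)))
  span <- resolve_lag_window(window, response_year)
  dates <- as.Date(series$date)
  sel <- dates >= span$start & dates <= span$end
  if (!any(sel)) {
    warning("lag window [", span$start, ", ", span$end, "] contains no data")
    return(NA_real_)
  }
  v <- series$value[sel]
  switch(fun, mean = mean(v), sum = sum(v), min = min(v), max = max(v))
}

#' Z-score standardization
#'
#' Centres and scales a covariate to mean 0 and sample standard deviation 1
#' (n-1 denominator). The centre/scale pair is attached as attributes so
#' prediction inputs can be standardized with the identical transformation.
#'
#' @param x Numeric vector (length >= 2) to standardize, or new data when
#'   `center` and `scale` are supplied.
#' @param center,scale Optional mean and SD from a previous call, reused
#'   verbatim (for prediction inputs).
#' @param name Covariate name used in error messages.
#' @return Standardized numeric vector with attributes `center` and `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL, name = "x") {
  if (is.null(center) != is.null(scale)) {
    stop("supply both center and scale, or neither")
  }
  if (is.null(center)) {
    if (length(x) < 2L) stop("standardize() requires length >= 2 for '", name, "'")
    center <- mean(x)
    scale <- stats::sd(x)
    if (scale == 0) stop("covariate '", name, "' has zero variance")
  }
  z <- (x - center) / scale
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}
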