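#' Read a lek-count series
#'
#' Reads comma-separated lek counts with header columns `lek_id`, `region_id`,
#' `year`, `count`. Counts are annual maxima of males counted at a lek;
#' missing counts are empty fields and are preserved as `NA`, never zero.
#' Within each lek, years are gap-filled to a contiguous index with `NA`
#' counts so the series can feed the latent-state model directly.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of class `lek_series` with columns `lek_id`,
#'   `region_id`, `year`, `count`, sorted by lek then year.
#' @export
read_lek_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("lek_id", "region_id", "year", "count")
  if (!setequal(names(df), expected)) {
    stop("unexpected columns: got {", paste(names(df), collapse = ", "),
         "}; expected {", paste(expected, collapse = ", "), "}")
  }
  df <- df[, expected]
  validate_lek_series(df)
}

#' Validate (and gap-fill) a lek-count table
#'
#' @param df A data.frame with columns `lek_id`, `region_id`, `year`, `count`.
#' @return A validated `lek_series` data.frame with per-lek contiguous years.
#' @export
validate_lek_series <- function(df) {
  df$count <- suppressWarnings(as.numeric(df$count))
  df$year <- as.integer(df$year)
  bad <- which(!is.na(df$count) & (df$count < 0 | df$count != floor(df$count)))
  if (length(bad)) {
    stop("invalid count at row ", bad[1], ": ", df$count[bad[1]],
         " (counts must be non-negative integers)")
  }
  key <- paste(df$lek_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (lek_id, year) pair: (", d$lek_id, ", ", d$year, ")")
  }
  regions <- tapply(df$region_id, df$lek_id, function(r) length(unique(r)))
  if (any(regions > 1)) {
    stop("lek ", names(regions)[regions > 1][1], " maps to multiple regions")
  }
  # gap-fill each lek to contiguous years with NA counts
  parts <- lapply(split(df, df$lek_id), function(d) {
    yrs <- seq(min(d$year), max(d$year))
    out <- data.frame(lek_id = d$lek_id[1], region_id = d$region_id[1],
                      year = yrs, count = NA_real_, stringsAsFactors = FALSE)
    out$count[match(d$year, yrs)] <- d$count
    out
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$lek_id, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("lek_series", "data.frame")
  out
}

#' Filter leks with sparse survey coverage
#'
#' Retains leks with at least `min_years` non-missing counts. The exact
#' inclusion rule used on the real lek database is not public, so the
#' threshold is a configurable stand-in (default 5).
#'
#' @param series A `lek_series` data.frame.
#' @param min_years Minimum number of observed (non-missing) counts (>= 1).
#' @param quiet Suppress the before/after message.
#' @return The filtered `lek_series`.
#' @export
filter_sparse_leks <- function(series, min_years = 5, quiet = FALSE) {
  stopifnot(min_years >= 1)
  n_obs <- tapply(!is.na(series$count), series$lek_id, sum)
  keep <- names(n_obs)[n_obs >= min_years]
  out <- series[series$lek_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lek_series", "data.frame")
  if (!quiet) {
    message("filter_sparse_leks: retained ", length(keep), " of ",
            length(n_obs), " leks (min_years = ", min_years, ")")
  }
  if (length(keep) == 0L) warning("no leks satisfy min_years = ", min_years)
  out
}

#' Read encounter histories
#'
#' Reads comma-separated daily-timestep encounter histories with columns
#' `unit_id`, `site_id`, `interval_start_doy`, `interval_end_doy`,
#' `exposure_days`, `outcome`, plus any number of covariate columns. Each row
#' is one exposure interval: `outcome = 1` means the unit (nest, brood, or
#' individual) survived the interval, `0` means it failed during it; a failure
#' terminates the unit's history. Day-of-year is 1-based and intervals are
#' closed, so `exposure_days = interval_end_doy - interval_start_doy`; the
#' stated column is cross-checked against the recomputation.
#'
#' @param path Path to a CSV file.
#' @param stage Life stage of every row: `"nest"`, `"brood"`, or `"adult"`.
#'   Adult-stage intervals must lie within days of year 75-242 (mid-March
#'   through end of August).
#' @return A `data.frame` of class `encounter_history` ordered by unit and
#'   interval start, with attribute `stage` and covariate columns preserved.
#' @export
read_encounter_histories <- function(path, stage = c("nest", "brood", "adult")) {
  stage <- match.arg(stage)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_encounter_histories(df, stage)
}

#' Validate an encounter-history table
#'
#' @param df Data.frame with the schema of [read_encounter_histories()].
#' @param stage Life stage label.
#' @return Validated, ordered `encounter_history` data.frame.
#' @export
validate_encounter_histories <- function(df, stage = c("nest", "brood", "adult")) {
  stage <- match.arg(stage)
  req <- c("unit_id", "site_id", "interval_start_doy", "interval_end_doy",
           "exposure_days", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  recomputed <- df$interval_end_doy - df$interval_start_doy
  if (any(recomputed != df$exposure_days)) {
    i <- which(recomputed != df$exposure_days)[1]
    stop("exposure_days mismatch at row ", i, ": stated ", df$exposure_days[i],
         ", end - start = ", recomputed[i])
  }
  if (any(df$exposure_days < 1)) {
    stop("exposure_days must be >= 1 (row ", which(df$exposure_days < 1)[1], ")")
  }
  if (!all(df$outcome %in% c(0, 1))) {
    stop("outcome must be 0 or 1 (row ", which(!df$outcome %in% c(0, 1))[1], ")")
  }
  if (stage == "adult") {
    out_of_window <- df$interval_start_doy < 75 | df$interval_end_doy > 242
    if (any(out_of_window)) {
      stop("adult-stage intervals must lie within days of year 75-242 (row ",
           which(out_of_window)[1], ")")
    }
  }
  df <- df[order(df$unit_id, df$interval_start_doy), , drop = FALSE]
  for (u in split(seq_len(nrow(df)), df$unit_id)) {
    starts <- df$interval_start_doy[u]
    ends <- df$interval_end_doy[u]
    if (length(u) > 1L && any(starts[-1] < ends[-length(u)])) {
      stop("overlapping intervals within unit ", df$unit_id[u[1]])
    }
    fails <- which(df$outcome[u] == 0)
    if (length(fails) > 1L || (length(fails) == 1L && fails != length(u))) {
      stop("unit ", df$unit_id[u[1]],
           " has intervals after a failure (outcome 0 must terminate the history)")
    }
  }
  rownames(df) <- NULL
  attr(df, "stage") <- stage
  class(df) <- c("encounter_history", "data.frame")
  df
}

#' Covariate columns of an encounter-history table
#' @param histories An `encounter_history` data.frame.
#' @return Character vector of covariate column names (possibly empty).
#' @export
covariate_names <- function(histories) {
  setdiff(names(histories),
          c("unit_id", "site_id", "interval_start_doy", "interval_end_doy",
            "exposure_days", "outcome", "stage"))
}

#' Write / read a posterior summary table
#'
#' Serializes a posterior summary (one row per parameter: mean, SD, 2.5th,
#' 50th and 97.5th percentiles, R-hat and pd) as CSV with a fixed column
#' order, so tables round-trip exactly at the stated precision.
#'
#' @param summary A data.frame as returned by [posterior_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(summary, path) {
  cols <- c("parameter", "mean", "sd", "q2.5", "q50", "q97.5", "rhat", "pd")
  miss <- setdiff(cols, names(summary))
  if (length(miss)) stop("summary is missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(summary[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}
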