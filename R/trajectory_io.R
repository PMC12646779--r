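#' GPS trajectory container
#'
#' One animal's timestamped, projected relocations. Timestamps must be
#' strictly increasing and coordinates finite; the movement metrics further
#' require a span of at least 21 consecutive months (checked at windowing,
#' not construction, so partial records can still be inspected).
#'
#' @param animal_id Animal identifier.
#' @param timestamp `POSIXct` (UTC) fix times, strictly increasing.
#' @param x,y Projected coordinates in metres.
#' @param loc_error_sd Location-error SD in metres (scalar or per fix).
#' @return An object of class `trajectory` with elements `animal_id` and
#'   `fixes` (data.frame: `timestamp`, `x`, `y`, `loc_error_sd`).
#' @export
trajectory <- function(animal_id, timestamp, x, y, loc_error_sd = 20) {
  stopifnot(inherits(timestamp, "POSIXct"),
            length(timestamp) == length(x), length(x) == length(y))
  if (length(timestamp) == 0) stop("empty trajectory")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite coordinates in trajectory ", animal_id)
  if (any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps not strictly increasing for ", animal_id)
  attr(timestamp, "tzone") <- "UTC"
  fixes <- data.frame(timestamp = timestamp, x = x, y = y,
                      loc_error_sd = rep_len(loc_error_sd, length(x)))
  structure(list(animal_id = as.character(animal_id), fixes = fixes),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  f <- x$fixes
  cat(sprintf("trajectory '%s': %d fixes, %s .. %s\n", x$animal_id, nrow(f),
              format(min(f$timestamp), "%Y-%m-%d"),
              format(max(f$timestamp), "%Y-%m-%d")))
  invisible(x)
}

#' Write trajectories to delimited text
#'
#' One CSV with columns `animal_id`, `timestamp` (ISO-8601, UTC), `x`, `y`,
#' `loc_error_sd`.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = format(tr$fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               x = tr$fixes$x, y = tr$fixes$y,
               loc_error_sd = tr$fixes$loc_error_sd)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate trajectories from delimited text
#'
#' Rows are grouped by `animal_id` and sorted by time. Duplicate timestamps
#' within an animal are collapsed to the first occurrence with a warning.
#' Animals whose records cannot be validated (unparseable timestamps,
#' non-finite coordinates) are rejected; the returned list carries a
#' `rejected` attribute naming them with the reason.
#'
#' @param path CSV file with columns `animal_id`, `timestamp`, `x`, `y` and
#'   optionally `loc_error_sd`.
#' @param sep Field separator (default `","`).
#' @param default_loc_error_sd Used when the file lacks `loc_error_sd`.
#' @return Named list of [trajectory()] objects.
#' @export
read_trajectories <- function(path, sep = ",", default_loc_error_sd = 20) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("animal_id", "timestamp", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(df$loc_error_sd)) df$loc_error_sd <- default_loc_error_sd
  out <- list()
  rejected <- character()
  for (id in unique(df$animal_id)) {
    sub <- df[df$animal_id == id, ]
    ts <- tryCatch(
      as.POSIXct(sub$timestamp, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                "%Y-%m-%d %H:%M:%S")),
      error = function(e) rep(as.POSIXct(NA), nrow(sub)))
    if (anyNA(ts)) {
      rejected[id] <- "unparseable timestamp"
      next
    }
    ord <- order(ts)
    sub <- sub[ord, ]
    ts <- ts[ord]
    dup <- duplicated(as.numeric(ts))
    if (any(dup)) {
      warning(sum(dup), " duplicated timestamp(s) dropped for animal ", id)
      sub <- sub[!dup, ]
      ts <- ts[!dup]
    }
    tr <- tryCatch(trajectory(id, ts, sub$x, sub$y, sub$loc_error_sd),
                   error = function(e) conditionMessage(e))
    if (is.character(tr)) {
      rejected[id] <- tr
      next
    }
    out[[id]] <- tr
  }
  if (length(rejected))
    warning("rejected ", length(rejected), " animal(s): ",
            paste(names(rejected), collapse = ", "))
  attr(out, "rejected") <- rejected
  out
}

#' Season window definitions
#'
#' Summer is 1 June - 31 August; winter is 1 December - 28/29 February, with
#' the winter of year `t` spanning Dec `t` - Feb `t+1`. Monthly windows are
#' calendar months indexed sequentially from the first month of data. Season
#' boundaries fall at 00:00 UTC.
#'
#' @param summer_months,winter_months Integer month numbers.
#' @return An object of class `season_windows`.
#' @export
season_windows <- function(summer_months = 6:8, winter_months = c(12L, 1L, 2L)) {
  structure(list(summer_months = as.integer(summer_months),
                 winter_months = as.integer(winter_months)),
            class = "season_windows")
}

# sequential month index relative to the first month of the record
month_index <- function(dates, origin) {
  yr <- as.integer(format(dates, "%Y"))
  mon <- as.integer(format(dates, "%m"))
  oy <- as.integer(format(origin, "%Y"))
  om <- as.integer(format(origin, "%m"))
  (yr - oy) * 12L + (mon - om) + 1L
}

subset_trajectory <- function(traj, keep) {
  f <- traj$fixes[keep, , drop = FALSE]
  if (nrow(f) == 0) return(NULL)
  trajectory(traj$animal_id, f$timestamp, f$x, f$y, f$loc_error_sd)
}

#' Partition a trajectory into seasonal and monthly windows
#'
#' Returns the per-year summer and winter sub-trajectories and the sequence
#' of monthly sub-trajectories. Windows with fewer than `min_fixes`
#' relocations are flagged absent (listed in `$absent`, `NULL` entries kept
#' in `$monthly` so sequential month indices stay aligned). An animal is
#' `complete` — classifiable — only when it has at least two usable summers,
#' two usable winters, and a record spanning at least 21 calendar months.
#'
#' @param traj A [trajectory()].
#' @param windows A [season_windows()].
#' @param min_fixes Minimum relocations for a usable window (default 30,
#'   guarding degenerate density estimates).
#' @return An object of class `season_split`: list with `summer` and
#'   `winter` (named lists of sub-trajectories, by year / winter-onset
#'   year), `monthly` (list over sequential month index; `NULL` where
#'   absent), `month_labels`, `absent`, `n_months`, `complete`.
#' @export
split_windows <- function(traj, windows = season_windows(), min_fixes = 30) {
  stopifnot(inherits(traj, "trajectory"), inherits(windows, "season_windows"))
  f <- traj$fixes
  dates <- as.Date(f$timestamp, tz = "UTC")
  yr <- as.integer(format(dates, "%Y"))
  mon <- as.integer(format(dates, "%m"))
  origin <- as.Date(format(min(dates), "%Y-%m-01"))
  midx <- month_index(dates, origin)
  n_months <- max(midx)
  absent <- character()

  monthly <- vector("list", n_months)
  month_labels <- format(seq(origin, by = "1 month", length.out = n_months),
                         "%Y-%m")
  for (m in seq_len(n_months)) {
    keep <- midx == m
    if (sum(keep) >= min_fixes) {
      monthly[[m]] <- subset_trajectory(traj, keep)
    } else {
      absent <- c(absent, paste0("month_", month_labels[m]))
    }
  }

  # expected seasonal windows are enumerated from the record span, so that
  # a window the record should contain but has no fixes in is flagged absent
  d0 <- min(dates)
  d1 <- max(dates)
  yr_range <- seq(as.integer(format(d0, "%Y")) - 1L,
                  as.integer(format(d1, "%Y")))
  overlaps <- function(a, b) a <= d1 && b >= d0

  summer <- list()
  for (y in yr_range) {
    if (!overlaps(as.Date(paste0(y, "-06-01")), as.Date(paste0(y, "-08-31"))))
      next
    keep <- yr == y & mon %in% windows$summer_months
    if (sum(keep) >= min_fixes) {
      summer[[as.character(y)]] <- subset_trajectory(traj, keep)
    } else {
      absent <- c(absent, paste0("summer_", y))
    }
  }

  winter <- list()
  wy <- winter_year_of(mon, yr)
  for (y in yr_range) {
    if (!overlaps(as.Date(paste0(y, "-12-01")),
                  as.Date(paste0(y + 1, "-03-01")) - 1))
      next
    keep <- mon %in% windows$winter_months & wy == y
    if (sum(keep) >= min_fixes) {
      winter[[as.character(y)]] <- subset_trajectory(traj, keep)
    } else {
      absent <- c(absent, paste0("winter_", y))
    }
  }

  complete <- length(summer) >= 2 && length(winter) >= 2 && n_months >= 21
  structure(list(summer = summer, winter = winter, monthly = monthly,
                 month_labels = month_labels, absent = absent,
                 n_months = n_months, complete = complete),
            class = "season_split")
}

#' @export
print.season_split <- function(x, ...) {
  cat(sprintf("season_split: %d summers, %d winters, %d months (%d absent windows), %s\n",
              length(x$summer), length(x$winter), x$n_months, length(x$absent),
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}
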