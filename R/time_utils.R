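# Clock-time arithmetic. All times are integer minutes since midnight in
# [0, 1440); intervals are half-open [start, end) and may wrap midnight.

MINUTES_PER_DAY <- 1440L

#' Parse a clock time to minutes since midnight
#'
#' Accepts `"HH:MM"` strings (24h) or bare numbers already in minutes.
#'
#' @param x character vector of `"HH:MM"` times, or a numeric vector of
#'   minutes since midnight.
#' @return integer vector of minutes in `[0, 1440)`.
#' @examples
#' parse_clock("07:30")   # 450
#' parse_clock(c("00:00", "23:59"))
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(round(x))
  } else {
    ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
    if (!all(ok)) {
      stop("invalid clock time(s): ", paste(x[!ok], collapse = ", "), call. = FALSE)
    }
    hh <- as.integer(sub(":.*", "", x))
    mm <- as.integer(sub(".*:", "", x))
    m <- hh * 60L + mm
  }
  if (any(m < 0L | m >= MINUTES_PER_DAY)) {
    stop("clock time out of [00:00, 24:00): ", paste(m[m < 0L | m >= MINUTES_PER_DAY], collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m integer vector of minutes in `[0, 1440)`.
#' @return character vector of `"HH:MM"` strings.
#' @export
format_clock <- function(m) {
  m <- as.integer(m) %% MINUTES_PER_DAY
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# Circular (24h-wrapped) gap between two times, in minutes: the shorter
# way around the clock. Used for pairwise spacing checks.
circular_gap <- function(a, b) {
  d <- abs(a - b) %% MINUTES_PER_DAY
  pmin(d, MINUTES_PER_DAY - d)
}

# Normalize an interval that may wrap midnight into a list of non-wrapping
# half-open [start, end) pieces split at 00:00. A zero-length interval
# (start == end) yields nothing.
split_interval <- function(start, end) {
  if (start == end) return(list())
  if (start < end) return(list(c(start, end)))
  # wraps midnight
  out <- list()
  if (start < MINUTES_PER_DAY) out <- c(out, list(c(start, MINUTES_PER_DAY)))
  if (end > 0L) out <- c(out, list(c(0L, end)))
  out
}

# Complement of a set of non-wrapping [start,end) intervals within the day.
complement_intervals <- function(ivs) {
  if (length(ivs) == 0L) return(list(c(0L, MINUTES_PER_DAY)))
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- list()
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    if (m[i, 1L] > cur) out <- c(out, list(c(cur, m[i, 1L])))
    cur <- max(cur, m[i, 2L])
  }
  if (cur < MINUTES_PER_DAY) out <- c(out, list(c(cur, MINUTES_PER_DAY)))
  out
}

# Is time t inside any of the non-wrapping [start,end) intervals?
in_intervals <- function(t, ivs) {
  if (length(ivs) == 0L) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (iv in ivs) res <- res | (t >= iv[1L] & t < iv[2L])
  res
}

# Minutes of overlap between point t (a single dose instant) and intervals:
# for penalty purposes a dose inside a forbidden window is scored by its
# depth (distance to the nearest exit), so nudging toward the boundary
# always lowers the penalty.
forbidden_depth <- function(t, ivs) {
  depth <- rep(0, length(t))
  for (iv in ivs) {
    inside <- t >= iv[1L] & t < iv[2L]
    depth[inside] <- pmax(depth[inside], pmin(t[inside] - iv[1L] + 1, iv[2L] - t[inside]))
  }
  depth
}
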