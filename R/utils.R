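# Angle and time helpers shared across modules.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @keywords internal
#' Wrap an angle into [0, 360).
wrap360 <- function(a) a %% 360

#' @keywords internal
#' Signed smallest difference a - b between two azimuths, in (-180, 180].
azimuthDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Parse an ISO-8601 timestamp with explicit UTC offset
#'
#' Timestamps in session files carry an explicit offset
#' (`2012-07-09T13:48:00-08:00`); all internal computation (in particular the
#' solar ephemeris) is done in UTC.
#'
#' @param x character timestamp(s), `YYYY-mm-ddTHH:MM:SS+HH:MM` (seconds and
#'   the colon in the offset optional; a trailing `Z` means UTC).
#' @return `POSIXct` in UTC with a `utcOffset` attribute (hours).
#' @export
parseTimestamp <- function(x) {
  x <- as.character(x)
  x1 <- sub("Z$", "+0000", x)
  x1 <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x1)
  # allow missing seconds
  noSec <- grepl("T[0-9]{2}:[0-9]{2}[+-]", x1)
  x1[noSec] <- sub("(T[0-9]{2}:[0-9]{2})", "\\1:00", x1[noSec])
  t <- as.POSIXct(strptime(x1, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
  if (anyNA(t)) {
    stop("unparseable timestamp(s): ",
         paste(x[is.na(t)], collapse = ", "), call. = FALSE)
  }
  off <- sub("^.*([+-][0-9]{4})$", "\\1", x1)
  offH <- ifelse(grepl("^[+-][0-9]{4}$", off),
                 sign(as.numeric(off)) * (abs(as.numeric(off)) %/% 100 +
                                            (abs(as.numeric(off)) %% 100) / 60),
                 0)
  attr(t, "utcOffset") <- offH
  t
}

#' Format a UTC time as an ISO-8601 string with offset
#'
#' @param t `POSIXct` (UTC).
#' @param utcOffset offset in hours to render the local time with (default 0).
#' @return character timestamp.
#' @export
formatTimestamp <- function(t, utcOffset = 0) {
  loc <- t + utcOffset * 3600
  hh <- sprintf("%+03d", as.integer(trunc(utcOffset)))
  mm <- sprintf("%02d", as.integer(round(abs(utcOffset - trunc(utcOffset)) * 60)))
  paste0(format(loc, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), hh, ":", mm)
}

#' Append a timestamped line to a session log
#'
#' One line per realized operation, mirroring the instrument-control log:
#' `<ISO timestamp> [stage] message`.
#'
#' @param logFile path, or `NULL` to skip logging.
#' @param stage short stage label.
#' @param message free-text message.
#' @return the formatted line, invisibly.
#' @export
appendLog <- function(logFile, stage, message) {
  line <- sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  stage, message)
  if (!is.null(logFile)) cat(line, "\n", sep = "", file = logFile, append = TRUE)
  invisible(line)
}

# Run an expression with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
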