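#' Construct and validate a kinetic trace
#'
#' One well's cumulative luminescence time series with its condition
#' metadata. Rows are sorted by time; duplicate timestamps and negative
#' signals are rejected.
#'
#' @param times Time points in minutes.
#' @param signal Cumulative luminescence (ALU), same length as `times`.
#' @param construct Construct name.
#' @param mg_mM Added Mg2+ (mM).
#' @param k_mM Added K+ (mM).
#' @param replicate Replicate identifier.
#' @param lysate Lysate (extract) identifier.
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, construct, mg_mM, k_mM,
                          replicate = 1L, lysate = "lysate1") {
  missing_meta <- c(construct = missing(construct), mg_mM = missing(mg_mM),
                    k_mM = missing(k_mM))
  if (any(missing_meta)) {
    stop("missing metadata fields: ",
         paste(names(missing_meta)[missing_meta], collapse = ", "))
  }
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal)) {
    stop("times and signal must have equal length")
  }
  if (length(times) < 3L) stop("a kinetic trace needs at least 3 time points")
  if (anyNA(times) || anyNA(signal)) stop("times and signal must not contain NA")
  dup <- times[duplicated(times)]
  if (length(dup)) {
    stop(sprintf("duplicate timestamp(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  ord <- order(times)
  times <- times[ord]
  signal <- signal[ord]
  if (any(signal < 0)) stop("negative luminescence signal")
  structure(
    list(times = times, signal = signal,
         meta = list(construct = as.character(construct),
                     mg_mM = as.numeric(mg_mM), k_mM = as.numeric(k_mM),
                     replicate = replicate, lysate = as.character(lysate))),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<kinetic_trace> %s, %g mM Mg, %g mM K, rep %s, %s: %d reads over %g-%g min\n",
              m$construct, m$mg_mM, m$k_mM, m$replicate, m$lysate,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$times, x$signal, type = "l", xlab = "time (min)",
                 ylab = "luminescence (ALU)",
                 main = sprintf("%s, %g mM Mg", x$meta$construct, x$meta$mg_mM),
                 ...)
  invisible(x)
}

#' Maximal synthesis rate of a kinetic trace
#'
#' The maximal gain of luciferase activity per minute: an ordinary
#' least-squares slope is computed on every contiguous window of duration
#' `window_minutes`, and the maximum is returned together with the start of
#' the winning window (ties broken by earliest window). Negative maxima are
#' clamped to 0 -- synthesis rates are physical. A window of one sampling
#' interval recovers simple per-minute differences.
#'
#' @param trace A [kinetic_trace()].
#' @param window_minutes Window duration in minutes (default 5); must span at
#'   least 2 sampling intervals.
#' @return Object of class `rate_point`: list with `max_rate` (ALU/min),
#'   `window_start` (min), and the trace metadata (`construct`, `mg_mM`,
#'   `k_mM`, `replicate`, `lysate`).
#' @export
max_synthesis_rate <- function(trace, window_minutes = 5) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times
  y <- trace$signal
  dt <- min(diff(t))
  if (window_minutes < 2 * dt) {
    stop("window_minutes must span at least 2 sampling intervals")
  }
  if (window_minutes > max(t) - min(t)) {
    stop("trace is shorter than the requested window")
  }
  best <- -Inf
  best_start <- t[1L]
  for (i in seq_along(t)) {
    j <- which(t <= t[i] + window_minutes + 1e-9)
    j <- j[j >= i]
    if (length(j) < 3L || t[max(j)] - t[i] < window_minutes - 1e-9) next
    tt <- t[j]
    yy <- y[j]
    slope <- stats::cov(tt, yy) / stats::var(tt)
    if (slope > best + 1e-12) {
      best <- slope
      best_start <- t[i]
    }
  }
  if (!is.finite(best)) stop("no complete window fits inside the trace")
  structure(
    list(max_rate = max(0, best), window_start = best_start,
         mg_mM = trace$meta$mg_mM, k_mM = trace$meta$k_mM,
         construct = trace$meta$construct, replicate = trace$meta$replicate,
         lysate = trace$meta$lysate),
    class = "rate_point"
  )
}

#' @export
print.rate_point <- function(x, ...) {
  cat(sprintf("<rate_point> %s at %g mM Mg, %g mM K: %.4g ALU/min (window from %g min)\n",
              x$construct, x$mg_mM, x$k_mM, x$max_rate, x$window_start))
  invisible(x)
}

#' Read a long-format table of kinetic traces
#'
#' Accepts a data.frame or a CSV/TSV path with columns `time_min`,
#' `signal_alu`, `construct`, `mg_mM`, `k_mM`, `replicate`, `lysate` (the
#' latter defaulting to `"lysate1"` when absent) and splits it into one
#' validated [kinetic_trace()] per well.
#'
#' @param x data.frame or file path.
#' @return List of `kinetic_trace` objects.
#' @export
read_trace_table <- function(x) {
  if (is.character(x)) {
    sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
    x <- utils::read.table(x, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  needed <- c("time_min", "signal_alu", "construct", "mg_mM", "k_mM", "replicate")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("trace table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"lysate" %in% names(x)) x$lysate <- "lysate1"
  key <- interaction(x$construct, x$mg_mM, x$k_mM, x$replicate, x$lysate,
                     drop = TRUE)
  lapply(split(x, key), function(w) {
    kinetic_trace(w$time_min, w$signal_alu, construct = w$construct[1L],
                  mg_mM = w$mg_mM[1L], k_mM = w$k_mM[1L],
                  replicate = w$replicate[1L], lysate = w$lysate[1L])
  })
}

#' Read a wide plate-reader export
#'
#' Accepts the time-by-wells layout most plate readers emit: a table whose
#' first column is `time_min` and remaining columns are wells, plus a
#' well-map TSV (or data.frame) with columns `well`, `construct`, `mg_mM`,
#' `k_mM`, `replicate` and optionally `lysate`.
#'
#' @param x Wide table: data.frame or CSV/TSV path.
#' @param well_map Well metadata: data.frame or TSV path.
#' @return List of [kinetic_trace()] objects, one per mapped well.
#' @export
read_trace_wide <- function(x, well_map) {
  if (is.character(x)) {
    sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
    x <- utils::read.table(x, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  if (is.character(well_map)) {
    well_map <- utils::read.table(well_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), is.data.frame(well_map))
  if (names(x)[1L] != "time_min") {
    stop("wide trace table must start with a time_min column")
  }
  needed <- c("well", "construct", "mg_mM", "k_mM", "replicate")
  miss <- setdiff(needed, names(well_map))
  if (length(miss)) {
    stop("well map lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"lysate" %in% names(well_map)) well_map$lysate <- "lysate1"
  absent <- setdiff(well_map$well, names(x)[-1L])
  if (length(absent)) {
    stop("well(s) missing from the trace table: ",
         paste(absent, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(well_map)), function(i) {
    w <- well_map[i, ]
    kinetic_trace(x$time_min, x[[w$well]], construct = w$construct,
                  mg_mM = w$mg_mM, k_mM = w$k_mM, replicate = w$replicate,
                  lysate = w$lysate)
  })
  stats::setNames(out, well_map$well)
}

#' Maximal synthesis rates for a set of traces
#'
#' @param traces List of [kinetic_trace()] objects (or a table accepted by
#'   [read_trace_table()]).
#' @param window_minutes Passed to [max_synthesis_rate()].
#' @return data.frame with one row per well: `construct`, `mg_mM`, `k_mM`,
#'   `replicate`, `lysate`, `max_rate`, `window_start`.
#' @export
rate_table <- function(traces, window_minutes = 5) {
  if (!is.list(traces) || inherits(traces, "data.frame")) {
    traces <- read_trace_table(traces)
  }
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    rp <- max_synthesis_rate(tr, window_minutes)
    data.frame(construct = rp$construct, mg_mM = rp$mg_mM, k_mM = rp$k_mM,
               replicate = rp$replicate, lysate = rp$lysate,
               max_rate = rp$max_rate, window_start = rp$window_start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$construct, out$k_mM, out$mg_mM, out$replicate), , drop = FALSE]
}
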