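#' Stimulation protocols
#'
#' A stimulation protocol describes how an assembly is driven over time.
#' Two modes are supported, because both occur in practice: *clamping*
#' (forcing selected neurons persistently active or silent, the usual model
#' of a sustained stimulus) and *additive input* (a per-neuron term `S_i`
#' added to the input accumulation before thresholding).  A protocol is a
#' list of windows; each window is active on the half-open time interval
#' `[start, end)` (0-based, so a window starting at 0 also constrains the
#' initial state).
#'
#' @param ... windows created with [protocol_window()].
#' @param windows alternatively, a list of windows.
#' @return an object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol(protocol_window(0, Inf, clamp_on = 1:3))
#' @export
stimulus_protocol <- function(..., windows = NULL) {
  windows <- c(list(...), windows)
  for (w in windows) {
    if (!inherits(w, "protocol_window")) {
      stop_param("all protocol elements must be created with protocol_window()")
    }
  }
  structure(list(windows = windows), class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param start,end half-open time interval `[start, end)` during which the
#'   window applies; `end = Inf` means "until the end of the run".
#' @param clamp_on,clamp_off neuron indices forced to 1 (resp. 0) while the
#'   window is active; the two sets must be disjoint.
#' @param external numeric vector of additive inputs `S_i` (length-n, or a
#'   named subset via a full-length vector with zeros elsewhere).
#' @export
protocol_window <- function(start, end = Inf, clamp_on = integer(),
                            clamp_off = integer(), external = NULL) {
  if (start < 0 || (is.finite(end) && end <= start)) {
    stop_param("window must satisfy 0 <= start < end")
  }
  clamp_on <- as.integer(clamp_on)
  clamp_off <- as.integer(clamp_off)
  if (length(intersect(clamp_on, clamp_off))) {
    stop_param("clamp_on and clamp_off overlap within a window")
  }
  structure(list(start = start, end = end, clamp_on = clamp_on,
                 clamp_off = clamp_off, external = external),
            class = "protocol_window")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", length(x$windows), "window(s)\n")
  for (w in x$windows) {
    cat(sprintf("  [%s, %s): clamp_on %d, clamp_off %d, external %s\n",
                format(w$start), format(w$end), length(w$clamp_on),
                length(w$clamp_off),
                if (is.null(w$external)) "none" else "yes"))
  }
  invisible(x)
}

# Validate protocol indices against a network of n neurons.
validate_protocol <- function(protocol, n) {
  if (is.null(protocol)) return(invisible(NULL))
  if (is.function(protocol)) return(invisible(NULL))
  stopifnot(inherits(protocol, "stimulus_protocol"))
  for (w in protocol$windows) {
    idx <- c(w$clamp_on, w$clamp_off)
    if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
      stop_param("protocol clamp index out of range 1..", n)
    }
    if (!is.null(w$external) && length(w$external) != n) {
      stop_param("protocol external input must have length n = ", n)
    }
  }
  invisible(NULL)
}

# Resolve the controls applying at time t.  A protocol may also be a plain
# function(t) returning list(clamp_on=, clamp_off=, external=), which is how
# time-varying drives (e.g. periodic input trains) are expressed internally.
protocol_at <- function(protocol, t, n) {
  none <- list(clamp_on = integer(), clamp_off = integer(), external = NULL)
  if (is.null(protocol)) return(none)
  if (is.function(protocol)) {
    ctl <- protocol(t)
    if (is.null(ctl)) return(none)
    return(list(clamp_on = as.integer(ctl$clamp_on %||% integer()),
                clamp_off = as.integer(ctl$clamp_off %||% integer()),
                external = ctl$external))
  }
  on <- integer(); off <- integer(); ext <- NULL
  for (w in protocol$windows) {
    if (t >= w$start && t < w$end) {
      on <- union(on, w$clamp_on)
      off <- union(off, w$clamp_off)
      if (!is.null(w$external)) {
        ext <- if (is.null(ext)) w$external else ext + w$external
      }
    }
  }
  if (length(intersect(on, off))) {
    stop_param("overlapping windows clamp the same neuron both on and off at t = ", t)
  }
  list(clamp_on = on, clamp_off = off, external = ext)
}

# First time index from which the protocol is time-invariant (all finite
# windows over, all infinite windows begun).  Cycle detection hashes states
# only from this point, since periodicity is undefined under a changing drive.
protocol_stationary_from <- function(protocol) {
  if (is.null(protocol)) return(0)
  if (is.function(protocol)) {
    return(attr(protocol, "stationary_from") %||% Inf)
  }
  t0 <- 0
  for (w in protocol$windows) {
    t0 <- max(t0, if (is.finite(w$end)) w$end else w$start)
  }
  t0
}
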