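#' Per-view respiratory phase signal
#'
#' Real-valued phases in `[1, 11)` indexing (and fractionally interpolating)
#' the 10 breathing phases, one value per projection view.
#'
#' @param phi numeric vector of phases in `[1, 11)`
#' @return an object of class `phase_signal`
#' @export
phase_signal <- function(phi) {
  if (any(phi < 1 | phi >= 11)) stop("phases must lie in [1, 11)")
  structure(list(phi = as.numeric(phi), n_views = length(phi)),
            class = "phase_signal")
}

#' @export
print.phase_signal <- function(x, ...) {
  cat(sprintf("phase signal: %d views, phi in [%.2f, %.2f]\n",
              x$n_views, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Periodic breathing signal
#'
#' The phase advances linearly through the cycle (`1 -> 11`, wrapping) a
#' fixed number of times over the scan; with the 1-cos phase-to-amplitude
#' mapping this gives sinusoidal-type regular breathing. The default cycle
#' count corresponds to a typical free-breathing rate (15 breaths) during a
#' 60 s scan.
#'
#' @param n_views number of views
#' @param cycles number of breathing cycles over the scan (> 0)
#' @param phase0 starting phase
#' @return a `phase_signal`
#' @export
periodic_signal <- function(n_views, cycles = 15, phase0 = 1) {
  if (cycles <= 0) stop("cycles must be positive")
  t <- (seq_len(n_views) - 1) / n_views
  phi <- 1 + ((phase0 - 1) + 10 * cycles * t) %% 10
  phase_signal(phi)
}

#' Non-periodic breathing signal
#'
#' Emulates irregular respiration during a short scan: a small number of
#' breathing cycles with drifting rate and amplitude, interrupted by
#' breath-hold plateaus and baseline shifts. The phase velocity is a
#' seeded piecewise process (slow segments, holds, occasional fast
#' recoveries), integrated and wrapped into `[1, 11)`. Reproducible given
#' the seed.
#'
#' @param n_views number of views
#' @param seed integer seed
#' @param scan_time nominal scan duration, s (sets segment lengths)
#' @param n_events number of velocity change-points
#' @return a `phase_signal`
#' @export
nonperiodic_signal <- function(n_views, seed = 1, scan_time = 60,
                               n_events = 6) {
  set.seed(seed)
  # change-points splitting the scan into segments with their own phase
  # velocity (cycles/s): slow and occasional fast breathing
  cuts <- sort(runif(n_events, 0.05, 0.95))
  bounds <- c(0, cuts, 1)
  kind <- sample(c("slow", "fast"), n_events + 1, replace = TRUE,
                 prob = c(0.65, 0.35))
  vel <- vapply(kind, function(k) switch(k,
    slow = runif(1, 0.06, 0.15),
    fast = runif(1, 0.22, 0.38)), 0)
  t <- (seq_len(n_views) - 1) / (n_views - 1) * scan_time
  seg <- findInterval(t / scan_time, bounds, rightmost.closed = TRUE)
  v_view <- vel[seg]
  # one extended breath-hold plateau (about a third of the scan) plus a
  # shorter one, the hallmark of highly irregular respiration
  hold_len <- round(0.32 * n_views)
  hold_start <- round(runif(1, 0.15, 0.55) * n_views)
  v_view[hold_start:min(n_views, hold_start + hold_len)] <-
    runif(1, 0, 0.008)
  hold2 <- round(runif(1, 1, 0.1 * n_views))
  v_view[hold2:min(n_views, hold2 + round(0.08 * n_views))] <-
    runif(1, 0, 0.01)
  # integrate (cycles) and add a slow baseline drift
  dt <- c(0, diff(t))
  cyc <- cumsum(v_view * dt)
  drift <- 0.06 * sin(2 * pi * t / scan_time * runif(1, 0.5, 1.2) +
                        runif(1, 0, 2 * pi))
  phi <- 1 + (10 * (cyc + drift) + runif(1, 0, 10)) %% 10
  phase_signal(phi)
}

#' Write / read a phase signal as CSV (`view_index`, `phi`)
#' @param sig a `phase_signal`
#' @param path file path
#' @return `read_signal` returns a `phase_signal`
#' @export
write_signal <- function(sig, path) {
  utils::write.csv(data.frame(view_index = seq_len(sig$n_views),
                              phi = sig$phi), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  d <- utils::read.csv(path)
  phase_signal(d$phi)
}
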