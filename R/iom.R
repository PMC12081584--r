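#' Reference parameters of the beta-cell integrated oscillator model
#'
#' Loads the packaged reference parameterization (membrane currents, calcium
#' handling, glycolytic oscillator, nucleotide exchange and the K(ATP)
#' open-probability constants) and returns it as a flat named list. `Ktt`,
#' the dissociation constant governing ATP4- inhibition of the K(ATP)
#' channel, is the perturbation handle of the pipeline: its reference value
#' is 1 (model concentration units; quoted as 1 mM where the perturbation to
#' 0.96 is discussed).
#'
#' @param ktt override for the Ktt dissociation constant (default: file value).
#' @param overrides named list of further parameter overrides.
#' @param file optional path to an alternative JSON parameter file with the
#'   same layout as the packaged one.
#' @return A flat named list of parameters with an `initial_state` attribute.
#' @export
iom_params <- function(ktt = NULL, overrides = list(), file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "iom_reference_params.json",
                        package = "cholkatp", mustWork = TRUE)
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- c(raw$membrane, raw$calcium, raw$metabolism, raw$katp)
  p <- lapply(p, as.numeric)
  if (!is.null(ktt)) p$ktt <- ktt
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  if (any(unlist(p[c("gca", "gk", "gkca", "gkatpbar")]) < 0))
    stop("conductances must be >= 0")
  if (p$ktt <= 0) stop("ktt must be > 0")
  attr(p, "initial_state") <- unlist(raw$initial_state)
  p
}

#' K(ATP) channel open probability
#'
#' Mg-nucleotide regulated open probability:
#' `o = (0.08 (1 + 2 MgADP/kdd) + 0.89 (MgADP/kdd)^2) /
#'  ((1 + MgADP/kdd)^2 (1 + ADP3-/ktd + ATP4-/Ktt))`
#' with the fixed speciation fractions MgADP = 0.165 ADP, ADP3- = 0.135 ADP,
#' ATP4- = 0.05 ATP. Strictly decreasing in ATP at fixed ADP; decreasing Ktt
#' (higher ATP affinity) lowers the open probability at any ATP > 0.
#'
#' @param ATP,ADP nucleotide concentrations (model units, >= 0); vectorised.
#' @param params parameter list from [iom_params()] (uses `fmgadp`, `fadp3`,
#'   `fatp4`, `kdd`, `ktd`, `ktt`).
#' @return Open probability in (0, 1].
#' @export
okatp <- function(ATP, ADP, params = iom_params()) {
  if (any(ATP < 0) || any(ADP < 0)) stop("concentrations must be >= 0")
  mgadp <- params$fmgadp * ADP / params$kdd
  adp3 <- params$fadp3 * ADP / params$ktd
  atp4 <- params$fatp4 * ATP / params$ktt
  (0.08 * (1 + 2 * mgadp) + 0.89 * mgadp^2) /
    ((1 + mgadp)^2 * (1 + adp3 + atp4))
}

# Fixed parameter order of the compiled right-hand side (src/iom.c).
iom_param_order <- c(
  "gca", "gk", "gkca", "gkatpbar", "vca", "vk", "cm", "vm", "sm", "vn", "sn",
  "taun", "kd", "fca", "alpha", "kpmca", "kserca", "pleak", "sigmav", "Jgk",
  "vpfk", "kpfk", "k1", "k2", "k3", "k4", "famp", "fatp", "ffbp", "fbt",
  "fmt", "vpdh", "kcapdh", "atot", "taua", "r_exch", "r1", "vg", "kg",
  "fmgadp", "fadp3", "fatp4", "kdd", "ktd", "ktt")

iom_param_vector <- function(params) {
  v <- unlist(params[iom_param_order])
  if (length(v) != length(iom_param_order) || anyNA(v))
    stop("incomplete parameter list")
  v
}

# Smolen PFK rate: 16 binding states of (AMP, FBP, F6P, ATP); catalysis from
# F6P-bound states, at full rate when an activator (AMP or FBP) is bound and
# at fraction kpfk otherwise.
pfk_rate <- function(f6p, fbp, amp, atp, p) {
  wamp <- amp / p$k1
  wfbp <- fbp / p$k2
  wf6p <- f6p^2 / p$k3
  watp <- atp^2 / p$k4
  # subsets; interaction factors divide the product for each bound pair
  w0000 <- 1
  w1000 <- wamp
  w0100 <- wfbp
  w0010 <- wf6p
  w0001 <- watp
  w1100 <- wamp * wfbp
  w1010 <- wamp * wf6p / p$famp
  w1001 <- wamp * watp / p$fmt
  w0110 <- wfbp * wf6p / p$ffbp
  w0101 <- wfbp * watp / p$fbt
  w0011 <- wf6p * watp / p$fatp
  w1110 <- wamp * wfbp * wf6p / (p$famp * p$ffbp)
  w1101 <- wamp * wfbp * watp / (p$fmt * p$fbt)
  w1011 <- wamp * wf6p * watp / (p$famp * p$fmt * p$fatp)
  w0111 <- wfbp * wf6p * watp / (p$ffbp * p$fbt * p$fatp)
  w1111 <- wamp * wfbp * wf6p * watp / (p$famp * p$ffbp * p$fmt * p$fbt * p$fatp)
  total <- w0000 + w1000 + w0100 + w0010 + w0001 + w1100 + w1010 + w1001 +
    w0110 + w0101 + w0011 + w1110 + w1101 + w1011 + w0111 + w1111
  activated <- w1010 + w0110 + w1110 + w1011 + w0111 + w1111
  plain <- w0010 + w0011
  p$vpfk * (activated + p$kpfk * plain) / total
}

#' Right-hand side of the integrated oscillator model
#'
#' State: `v` (mV), `n` (delayed-rectifier gating), `c` (cytosolic Ca2+, uM),
#' `cer` (ER Ca2+, uM), `f6p`, `fbp` (glycolytic metabolites, uM), `adp` (uM;
#' ATP follows from the conserved nucleotide pool). Membrane potential is
#' driven by Ca2+, delayed-rectifier K+, Ca2+-activated K+ and K(ATP)
#' currents; cytosolic Ca2+ balances influx, SERCA uptake, ER leak and
#' plasma-membrane extrusion; glycolysis is the Smolen PFK oscillator; the
#' nucleotide exchange is stimulated by the PDH flux and loaded by
#' Ca2+-dependent ATPase consumption.
#'
#' @param state named numeric state vector.
#' @param params parameter list from [iom_params()].
#' @param t time (ms); unused (autonomous system) but kept for solver
#'   compatibility.
#' @return Named vector of time derivatives (per ms).
#' @export
iom_rhs <- function(state, params, t = 0) {
  if (anyNA(state)) stop("NaN in model state")
  p <- params
  v <- state[["v"]]; n <- state[["n"]]; c <- state[["c"]]; cer <- state[["cer"]]
  f6p <- state[["f6p"]]; fbp <- state[["fbp"]]; adp <- state[["adp"]]
  atp <- max(p$atot - adp, 1e-6)
  amp <- adp^2 / atp

  minf <- 1 / (1 + exp((p$vm - v) / p$sm))
  ninf <- 1 / (1 + exp((p$vn - v) / p$sn))
  ica <- p$gca * minf * (v - p$vca)
  ik <- p$gk * n * (v - p$vk)
  ikca <- p$gkca * (c^2 / (c^2 + p$kd^2)) * (v - p$vk)
  o <- okatp(atp, adp, p)
  ikatp <- p$gkatpbar * o * (v - p$vk)

  jmem <- -(p$alpha * ica + p$kpmca * c)
  jer <- p$pleak * (cer - c) - p$kserca * c

  jpfk <- pfk_rate(f6p, max(fbp, 0), amp, atp, p)
  jpdh <- p$vpdh * sqrt(max(fbp, 0)) * c / (c + p$kcapdh)
  gam <- p$vg * jpdh / (p$kg + jpdh)

  c(v = -(ica + ik + ikca + ikatp) / p$cm,
    n = (ninf - n) / p$taun,
    c = p$fca * (jmem + jer),
    cer = -p$fca * p$sigmav * jer,
    f6p = 0.3 * (p$Jgk - jpfk),
    fbp = jpfk - 0.5 * jpdh,
    adp = (atp - adp * exp((p$r_exch + gam) * (1 - c / p$r1))) / p$taua)
}

#' Integrate the beta-cell model
#'
#' Stiff-capable integration (deSolve lsoda) of [iom_rhs()] with dense output.
#' Deterministic given parameters and initial state.
#'
#' @param params parameter list from [iom_params()].
#' @param initial_state named state vector; defaults to the packaged
#'   reference initial state.
#' @param t_span simulated time in minutes.
#' @param dt_out output step in ms (default 10, fine enough to resolve
#'   individual spikes).
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @param compiled use the compiled right-hand side (default); `FALSE` falls
#'   back to the reference R implementation [iom_rhs()].
#' @return A list of class `iom_run`: `times` (min), `V` (mV), `n`, `Ca_c`,
#'   `Ca_er` (uM), `F6P`, `FBP`, `ADP`, `ATP` (uM), plus the parameters.
#' @useDynLib cholkatp
#' @export
iom_integrate <- function(params = iom_params(), initial_state = NULL,
                          t_span = 40, dt_out = 10, rtol = 1e-8, atol = 1e-10,
                          compiled = TRUE) {
  if (is.null(initial_state)) initial_state <- attr(params, "initial_state")
  y0 <- initial_state[c("v", "n", "c", "cer", "f6p", "fbp", "adp")]
  times <- seq(0, t_span * 60000, by = dt_out)
  sol <- if (compiled) {
    deSolve::ode(y = y0, times = times, func = "iom_derivs",
                 parms = iom_param_vector(params), dllname = "cholkatp",
                 initfunc = "iom_initpar", method = "lsoda",
                 rtol = rtol, atol = atol, maxsteps = 1000000)
  } else {
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, p) list(iom_rhs(y, p, t)),
                 parms = params, method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 1000000)
  }
  if (anyNA(sol[, "v"])) {
    diag <- utils::capture.output(deSolve::diagnostics.deSolve(sol))
    stop("solver failure: NaN in solution; ", paste(utils::tail(diag, 3), collapse = " "))
  }
  run <- list(times = sol[, "time"] / 60000, V = sol[, "v"], n = sol[, "n"],
              Ca_c = sol[, "c"], Ca_er = sol[, "cer"], F6P = sol[, "f6p"],
              FBP = sol[, "fbp"], ADP = sol[, "adp"],
              ATP = pmax(params$atot - sol[, "adp"], 0), params = params)
  class(run) <- "iom_run"
  run
}

#' @export
print.iom_run <- function(x, ...) {
  cat(sprintf("iom_run: %d samples over %.1f min (Ktt = %g)\n",
              length(x$times), max(x$times), x$params$ktt))
  invisible(x)
}

#' Detect spikes and bursts in a membrane-potential series
#'
#' Spikes are upward crossings of `spike_threshold`; bursts are maximal spike
#' groups whose inter-spike gaps stay below `silent_gap`; silent phases are
#' the spike-free intervals of at least `silent_gap` (window edges included).
#'
#' @param run an `iom_run`, or a list with `times` (min) and `V` (mV).
#' @param spike_threshold spike detection threshold, mV (default -40).
#' @param silent_gap minimum silent-phase duration, seconds (default 5).
#' @return A list with `spike_times` (min), `bursts` (data frame `start`,
#'   `end`, `n_spikes`), `silent_phases` (data frame `start`, `end`, minutes)
#'   and `n_spikes`.
#' @export
detect_events <- function(run, spike_threshold = -40, silent_gap = 5) {
  t <- run$times; v <- run$V
  if (length(v) < 2) stop("series too short for event detection")
  gap_min <- silent_gap / 60
  up <- which(v[-1] >= spike_threshold & v[-length(v)] < spike_threshold) + 1L
  spike_times <- t[up]
  bursts <- data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  if (length(spike_times)) {
    grp <- cumsum(c(1, diff(spike_times) >= gap_min))
    bursts <- do.call(rbind, lapply(split(spike_times, grp), function(s)
      data.frame(start = s[1], end = s[length(s)], n_spikes = length(s))))
    rownames(bursts) <- NULL
  }
  edges <- c(t[1], spike_times, t[length(t)])
  sp <- data.frame(start = edges[-length(edges)], end = edges[-1])
  sp <- sp[(sp$end - sp$start) >= gap_min, , drop = FALSE]
  rownames(sp) <- NULL
  list(spike_times = spike_times, bursts = bursts, silent_phases = sp,
       n_spikes = length(spike_times))
}

#' Classify beta-cell electrical activity
#'
#' Over a post-transient window: `silent` when no spikes occur, `bursting`
#' when at least two qualifying silent phases separate spike groups, else
#' `continuous_spiking`.
#'
#' @param run an `iom_run`.
#' @param window numeric `c(t_start, t_end)` in minutes, or `NULL` to discard
#'   the leading `transient_frac` of the run.
#' @param spike_threshold,silent_gap see [detect_events()].
#' @param transient_frac fraction of the run discarded as transient when
#'   `window` is `NULL` (default 0.2).
#' @return One of `"silent"`, `"bursting"`, `"continuous_spiking"`.
#' @export
classify_activity <- function(run, window = NULL, spike_threshold = -40,
                              silent_gap = 5, transient_frac = 0.2) {
  sub <- window_run(run, window, transient_frac)
  ev <- detect_events(sub, spike_threshold, silent_gap)
  if (ev$n_spikes == 0) return("silent")
  if (nrow(ev$silent_phases) >= 2) "bursting" else "continuous_spiking"
}

window_run <- function(run, window, transient_frac = 0.2) {
  t <- run$times
  if (is.null(window)) {
    window <- c(t[1] + transient_frac * (t[length(t)] - t[1]), t[length(t)])
  }
  keep <- t >= window[1] & t <= window[2]
  if (!any(keep)) stop("empty analysis window")
  out <- run
  for (nm in c("times", "V", "n", "Ca_c", "Ca_er", "F6P", "FBP", "ADP", "ATP"))
    if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]][keep]
  out
}

#' Slow calcium-oscillation metrics
#'
#' Smooths the cytosolic calcium series with a running mean (removing the
#' fast within-burst ripple), estimates the slow period from the first
#' autocorrelation peak of the down-sampled envelope, and reports the mean
#' per-cycle peak-to-trough amplitude. Oscillations are flagged abolished
#' when that amplitude falls below `amplitude_floor`.
#'
#' @param run an `iom_run`, or a list with `times` (min) and `Ca_c` (uM).
#' @param window analysis window in minutes (`NULL`: discard leading
#'   `transient_frac`).
#' @param smooth_window running-mean width in seconds (default 10).
#' @param amplitude_floor abolition threshold in uM (default 0.05).
#' @param transient_frac see [classify_activity()].
#' @return A list with `amplitude` (uM, peak-to-trough), `period` (min, `NA`
#'   when no slow oscillation is found), `mean_level` (uM) and `abolished`.
#' @export
ca_metrics <- function(run, window = NULL, smooth_window = 10,
                       amplitude_floor = 0.05, transient_frac = 0.2) {
  sub <- window_run(run, window, transient_frac)
  t <- sub$times; ca <- sub$Ca_c
  dt_min <- stats::median(diff(t))
  k <- max(1L, round(smooth_window / 60 / dt_min))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(ca, rep(1 / k, k), sides = 2))
  ok <- !is.na(sm)
  sm <- sm[ok]; ts <- t[ok]
  out <- list(amplitude = 0, period = NA_real_, mean_level = mean(ca),
              abolished = TRUE)
  if (stats::sd(sm) < 1e-12) return(out)
  # down-sample the envelope before autocorrelation
  ds <- max(1L, floor(0.25 / 60 / dt_min))
  e <- sm[seq(1, length(sm), by = ds)]
  dte <- dt_min * ds
  x <- e - mean(e)
  lag_max <- length(x) - 2L
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  neg <- which(ac < 0)
  period <- NA_real_
  if (length(neg)) {
    from <- neg[1]
    if (from < length(ac)) {
      pk <- from - 1L + which.max(ac[from:length(ac)])
      if (ac[pk] > 0.1) period <- (pk - 1) * dte
    }
  }
  out$period <- period
  if (!is.na(period)) {
    cyc_len <- max(2L, round(period / dte))
    n_cyc <- floor(length(e) / cyc_len)
    if (n_cyc >= 1) {
      amps <- vapply(seq_len(n_cyc), function(i) {
        seg <- e[((i - 1) * cyc_len + 1):(i * cyc_len)]
        max(seg) - min(seg)
      }, numeric(1))
      out$amplitude <- mean(amps)
    }
  } else {
    out$amplitude <- max(sm) - min(sm)
  }
  out$abolished <- out$amplitude < amplitude_floor
  out
}
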