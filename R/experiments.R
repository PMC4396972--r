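#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration describing a TCP experiment and validates it
#' against the model preconditions, collecting every violation into one
#' itemized error. Unknown keys are rejected.
#'
#' Expected layout:
#' \preformatted{
#' model:
#'   mu: 0.065
#'   gamma: 0.047
#'   f: 0
#'   Gamma_a: 1.5        # or a radiosensitivity + protocol block
#'   Gamma_q: 0.4
#' protocol:             # optional; {kind: zero|constant|fractionated, ...}
#'   kind: constant
#'   rate_gy_per_day: 2.75
#' populations: {n_a0: 100, n_q0: 100}
#' method: characteristics        # characteristics|gillespie|zaider-minerbo
#' times: {t_max: 24, t_step: 0.5}
#' runs: 10000                    # gillespie only
#' seed: 1                        # gillespie only
#' }
#'
#' @param path Path to a YAML file.
#' @return An object of class `experiment_config`: validated list with
#'   elements `params` ([two_compartment_params]), `protocol`, `n_a0`,
#'   `n_q0`, `method`, `times`, `runs`, `seed`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  known_top <- c("model", "protocol", "populations", "method", "times",
                 "runs", "seed")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) note(paste0("unknown top-level key(s): ",
                                 paste(extra, collapse = ", ")))

  m <- raw$model
  if (is.null(m)) note("missing 'model' block")
  known_model <- c("mu", "gamma", "f", "Gamma_a", "Gamma_q")
  extra <- setdiff(names(m), known_model)
  if (length(extra)) note(paste0("unknown model key(s): ",
                                 paste(extra, collapse = ", ")))
  for (k in c("mu", "gamma", "f")) {
    if (is.null(m[[k]])) note(paste0("model.", k, " is required"))
  }
  if (!is.null(m$f) && (m$f < 0 || m$f > 1)) {
    note(sprintf("model.f = %g outside the required range [0, 1]", m$f))
  }
  if (is.null(m$Gamma_a) || is.null(m$Gamma_q)) {
    note(paste0("model.Gamma_a and model.Gamma_q are required ",
                "(no protocol-derived death-rate block was given)"))
  }
  if (!is.null(m$Gamma_a) && m$Gamma_a < 0) note("model.Gamma_a must be >= 0")
  if (!is.null(m$Gamma_q) && m$Gamma_q < 0) note("model.Gamma_q must be >= 0")

  protocol <- dose_protocol_zero()
  if (!is.null(raw$protocol)) {
    protocol <- tryCatch(parse_protocol(raw$protocol),
                         error = function(e) { note(conditionMessage(e)); NULL })
  }

  pop <- raw$populations
  if (is.null(pop$n_a0) || is.null(pop$n_q0)) {
    note("populations.n_a0 and populations.n_q0 are required")
  } else if (pop$n_a0 < 0 || pop$n_q0 < 0) {
    note("initial populations must be nonnegative")
  }

  method <- raw$method %||% "characteristics"
  if (!method %in% c("characteristics", "gillespie", "zaider-minerbo")) {
    note(paste0("unknown method: ", method))
  }

  tm <- raw$times
  if (is.null(tm$t_max) || tm$t_max <= 0) note("times.t_max must be > 0")
  t_step <- tm$t_step %||% 0.5
  if (t_step <= 0) note("times.t_step must be > 0")

  runs <- raw$runs %||% 10000L
  if (runs < 1) note("runs must be >= 1")
  seed <- raw$seed
  if (method == "gillespie" && is.null(seed)) {
    seed <- sample.int(2^31 - 1, 1)
    message("no seed given for the Gillespie method; generated seed ", seed)
  }

  if (length(errs)) {
    stop("invalid experiment config:\n  - ", paste(errs, collapse = "\n  - "))
  }

  structure(list(
    params = two_compartment_params(m$mu, m$gamma, m$f, m$Gamma_a, m$Gamma_q),
    protocol = protocol,
    n_a0 = pop$n_a0, n_q0 = pop$n_q0,
    method = method,
    times = seq(0, tm$t_max, by = t_step),
    runs = as.integer(runs), seed = seed
  ), class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_protocol <- function(p) {
  kind <- p$kind %||% stop("protocol.kind is required")
  switch(kind,
    zero = dose_protocol_zero(),
    constant = dose_protocol_constant(
      p$rate_gy_per_day %||% stop("protocol.rate_gy_per_day is required")),
    fractionated = dose_protocol_fractionated(
      do.call(rbind, p$fractions %||% stop("protocol.fractions is required"))),
    stop("unknown protocol kind: ", kind))
}

#' Run a TCP experiment
#'
#' Dispatches a validated [load_experiment_config()] object to the selected
#' solver.
#'
#' @param config An `experiment_config`.
#' @return A [tcp_curve].
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$method,
    characteristics = tcp_curve_characteristics(
      config$params, config$n_a0, config$n_q0, config$times),
    gillespie = estimate_tcp(
      config$params, config$n_a0, config$n_q0, config$times,
      M = config$runs, seed = config$seed),
    `zaider-minerbo` = {
      if (config$n_q0 > 0 || config$params$f != 1) {
        warning("the Zaider-Minerbo reference is the one-compartment ",
                "(f = 1, n_q0 = 0) limit; quiescent settings are ignored")
      }
      zp <- zm_params(config$params$mu, config$params$Gamma_a, config$n_a0)
      tcp_curve(config$times, zm_tcp(zp, config$times),
                method = "zaider-minerbo")
    })
}

#' Reproduce the package's reference experiments
#'
#' Re-runs the five reference computations of the two-compartment TCP study
#' and writes their data as CSV files into `outdir`:
#' \describe{
#'   \item{fig1}{Phase boundaries in the (Gamma_a, Gamma_q) plane for
#'     f = 0, 0.5, 0.7, 1 with mu = 0.065/day, gamma = 0.05/day.}
#'   \item{fig2}{Phase boundaries in the (mu, gamma) plane for
#'     f = 0, 0.5, 0.7, 0.9, 1 with Gamma_a = 1.5/day, Gamma_q = 0.4/day.}
#'   \item{fig3}{TCP(t) by the characteristics solver and the Gillespie
#'     estimator (clinical parameter set, 100 + 100 cells), plus their RMS
#'     distance at t = 0, 3, ..., 24 days.}
#'   \item{fig4}{TCP(t; f) for f = 0, 0.25, 0.5, 0.75, 1 at the clinical
#'     death rates (curves nearly coincide).}
#'   \item{fig5}{TCP(t; f) at low death rates Gamma_a = 0.08/day,
#'     Gamma_q = 0.1/day, where the asymmetric division factor separates
#'     the curves.}
#' }
#'
#' @param name One of `"fig1"` ... `"fig5"`.
#' @param outdir Output directory (created if needed).
#' @param runs Number of Gillespie runs (fig3).
#' @param seed Master seed for stochastic runs (fig3).
#' @return Invisibly, a list with the emitted data frame(s), any summary
#'   statistics, and the CSV path(s).
#' @export
run_figure <- function(name, outdir, runs = 10000, seed = 1) {
  name <- match.arg(name, c("fig1", "fig2", "fig3", "fig4", "fig5"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(name,
    fig1 = figure_phase_deaths(),
    fig2 = figure_phase_rates(),
    fig3 = figure_method_comparison(runs, seed),
    fig4 = figure_f_insensitive(),
    fig5 = figure_f_sensitive())
  paths <- character(0)
  for (nm in names(out$data)) {
    path <- file.path(outdir, paste0(name, "_", nm, ".csv"))
    write_csv_full(out$data[[nm]], path)
    paths <- c(paths, path)
  }
  invisible(c(out, list(paths = paths)))
}

figure_phase_deaths <- function() {
  mu <- 0.065; gamma <- 0.05
  grids <- lapply(c(0, 0.5, 0.7), function(f) {
    phase_boundary_death_rates(mu, gamma, f,
                               Gamma_a_grid = seq(0.0005, 0.1, by = 0.0005),
                               Gamma_q_max = 0.15)
  })
  # f = 1: criticality does not involve Gamma_q; vertical line Gamma_a = mu
  vert <- data.frame(f = 1, Gamma_a = mu,
                     Gamma_q = seq(0, 0.15, length.out = 61))
  list(data = list(boundary = do.call(rbind, c(grids, list(vert)))))
}

figure_phase_rates <- function() {
  Ga <- 1.5; Gq <- 0.4
  grids <- lapply(c(0, 0.5, 0.7, 0.9), function(f) {
    phase_boundary_rates(Ga, Gq, f, mu_grid = seq(0.05, 5, by = 0.05),
                         gamma_max = 50)
  })
  vert <- data.frame(f = 1, mu = Ga, gamma = seq(0, 5, length.out = 51))
  list(data = list(boundary = do.call(rbind, c(grids, list(vert)))))
}

clinical_params <- function(f = 0, gamma = 0.047) {
  two_compartment_params(mu = 0.065, gamma = gamma, f = f,
                         Gamma_a = 1.5, Gamma_q = 0.4)
}

figure_method_comparison <- function(runs, seed) {
  p <- clinical_params()
  grid <- seq(0, 24, by = 0.5)
  chr <- tcp_curve_characteristics(p, 100, 100, grid)
  gil <- estimate_tcp(p, 100, 100, grid, M = runs, seed = seed)
  sample_t <- seq(0, 24, by = 3)
  rms <- sqrt(mean((tcp_at(chr, sample_t) - tcp_at(gil, sample_t))^2))
  df <- cbind(as.data.frame(chr)[, c("t_days", "tcp")],
              tcp_gillespie = gil$tcp,
              ci_low = gil$ci_low, ci_high = gil$ci_high)
  names(df)[2] <- "tcp_characteristics"
  list(data = list(curves = df,
                   rms = data.frame(t_sampled = "0,3,...,24", rms = rms)),
       rms = rms)
}

figure_f_insensitive <- function() {
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  grid <- seq(0, 24, by = 0.1)
  curves <- do.call(rbind, lapply(fs, function(f) {
    cv <- tcp_curve_characteristics(clinical_params(f = f), 100, 100, grid)
    data.frame(f = f, t_days = grid, tcp = cv$tcp)
  }))
  spread <- max(tapply(curves$tcp, curves$t_days, function(v) diff(range(v))))
  list(data = list(curves = curves), max_spread = spread)
}

figure_f_sensitive <- function() {
  fs <- c(0, 0.5, 0.7, 1)
  grid <- seq(0, 365, by = 1)
  curves <- do.call(rbind, lapply(fs, function(f) {
    p <- two_compartment_params(mu = 0.065, gamma = 0.047, f = f,
                                Gamma_a = 0.08, Gamma_q = 0.1)
    cv <- tcp_curve_characteristics(p, 100, 100, grid)
    data.frame(f = f, t_days = grid, tcp = cv$tcp)
  }))
  list(data = list(curves = curves))
}

# CSV at full double precision so emitted files re-parse to the exact
# computed values
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
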