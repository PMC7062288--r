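# ParameterSet: the 16 searched model parameters plus fixed model constants.

#' Search ranges of the 16 variable model parameters
#'
#' Admissible range for every searched parameter, grouped as in the model:
#' tissue-related (recruitable progenitor density, white-matter directionality),
#' PDGF environment (initial bolus, diffusion, decay, secretion, consumption),
#' PDGF response (autocrine boost, half-max concentrations, recruited-cell
#' sensitivities) and cell-intrinsic trait distributions (intermitotic time and
#' migration speed, mean and spread).
#'
#' Units: `rho_R` % of local carrying capacity; `sigma_theta` degrees;
#' `p0`, `p_a`, `K_p`, `K_m` ng/mL; `D_p` cm^2/day; `r_d` 1/day;
#' `r_s` ng/mL/cell/day; `r_c` dimensionless fraction of `r_s`;
#' `tau_mean`, `sigma_tau` hours; `v_mean`, `sigma_v` um/h.
#'
#' @return data.frame with columns `param`, `lower`, `upper`.
#' @export
param_ranges <- function() {
  data.frame(
    param = c("rho_R", "sigma_theta", "p0", "D_p", "r_d", "r_s", "r_c",
              "p_a", "K_p", "K_m", "beta_p", "beta_m",
              "tau_mean", "sigma_tau", "v_mean", "sigma_v"),
    lower = c(0.1, 0, 100, 1e-6, 0, 10, 0,
              0.1, 5, 5, 0.1, 0.1,
              20, 0, 0, 0),
    upper = c(5, 45, 600, 1000e-6, 0.5, 400, 1,
              50, 300, 300, 1.0, 1.0,
              100, 100, 100, 100),
    stringsAsFactors = FALSE
  )
}

#' Build a model parameter set
#'
#' Collects the 16 searched parameters (see [param_ranges()]) together with the
#' fixed model constants: carrying capacity `kappa` per gray-matter density
#' node (white matter gets `2*kappa/3`), the engine time step `dt` (hours),
#' injection site and radius, end time, and the recruitable-cell activation
#' threshold. Unspecified parameters default to the midpoint of their range.
#'
#' @param ... named parameter values overriding the defaults.
#' @param kappa carrying capacity per 100 um density node in gray matter.
#' @param dt engine time step (h).
#' @param injection_site `c(x, y)` in micrometers, or `NULL` for domain center.
#' @param injection_radius radius (um) of the initial injection disc.
#' @param end_day simulated duration (days).
#' @param n_injected,n_recruited0 initial labeled cell counts.
#' @param range_check `"fail"`, `"warn"` or `"none"`: action when a searched
#'   parameter falls outside its admissible range.
#' @param quiescent_migrate should quiescent cells still migrate? Quiescence
#'   freezes only the cell cycle by default.
#' @param max_cells abort guard: a simulation exceeding this population size
#'   stops with an error (calibration scores such candidates as infeasible).
#' @return object of class `parameter_set` (a named list).
#' @export
parameter_set <- function(..., kappa = 100, dt = 0.25,
                          injection_site = NULL, injection_radius = 300,
                          end_day = 17, n_injected = 100, n_recruited0 = 100,
                          range_check = c("fail", "warn", "none"),
                          quiescent_migrate = TRUE, max_cells = 2e5) {
  range_check <- match.arg(range_check)
  rg <- param_ranges()
  p <- as.list(stats::setNames((rg$lower + rg$upper) / 2, rg$param))
  dots <- list(...)
  unknown <- setdiff(names(dots), rg$param)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots

  if (range_check != "none") {
    lo <- stats::setNames(rg$lower, rg$param); hi <- stats::setNames(rg$upper, rg$param)
    vals <- unlist(p[rg$param])
    bad <- rg$param[vals < lo[rg$param] | vals > hi[rg$param]]
    if (length(bad)) {
      msg <- paste0("parameter(s) outside admissible range: ",
                    paste(bad, collapse = ", "))
      if (range_check == "fail") stop(msg) else warning(msg)
    }
  }
  p$kappa <- kappa; p$dt <- dt
  p$injection_site <- injection_site; p$injection_radius <- injection_radius
  p$end_day <- end_day
  p$n_injected <- n_injected; p$n_recruited0 <- n_recruited0
  p$quiescent_migrate <- quiescent_migrate
  p$max_cells <- max_cells
  # fixed behavioural constants
  p$activation_threshold <- 5e-4   # ng/mL, strict '>' to activate
  p$gamma_cutoff <- 0.001          # skip activity below this response
  p$move_time_mean <- 42.6 / 60    # h, mean moving persistence
  p$stop_time_mean <- 70.1 / 60    # h, mean stopped persistence
  p$white_persistence_factor <- 1.5
  p$move_prob <- 0.5               # stop/move coin at persistence reset
  class(p) <- "parameter_set"
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  rg <- param_ranges()
  cat("<parameter_set>\n")
  for (nm in rg$param)
    cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  cat(sprintf("  kappa %g | dt %g h | end %g d | injection r %g um\n",
              x$kappa, x$dt, x$end_day, x$injection_radius))
  invisible(x)
}

#' Treatment schedule
#'
#' Anti-proliferative (AP) treatment kills, at every step while active, every
#' non-quiescent active cell whose inherited intermitotic time is below
#' `ap_threshold` (60 h). Anti-migratory (AM) treatment multiplies every
#' cell's effective migration speed by `am_factor` (0.1) while active.
#'
#' @param kind one of `"none"`, `"AP"`, `"AM"`, `"AP+AM"`.
#' @param start_day,end_day treatment window in days (default 14 to 42).
#' @param ap_threshold intermitotic-time kill threshold (h).
#' @param am_factor speed multiplier in (0, 1].
#' @return object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(kind = c("none", "AP", "AM", "AP+AM"),
                               start_day = 14, end_day = 42,
                               ap_threshold = 60, am_factor = 0.1) {
  kind <- match.arg(kind)
  if (kind != "none" && start_day >= end_day) stop("start_day must be < end_day")
  if (am_factor <= 0 || am_factor > 1) stop("am_factor must be in (0, 1]")
  structure(list(kind = kind, start_day = start_day, end_day = end_day,
                 ap_threshold = ap_threshold, am_factor = am_factor),
            class = "treatment_schedule")
}

treatment_active <- function(schedule, what, time_h) {
  if (is.null(schedule) || schedule$kind == "none") return(FALSE)
  on <- time_h >= schedule$start_day * 24 & time_h < schedule$end_day * 24
  on && grepl(what, schedule$kind, fixed = TRUE)
}
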