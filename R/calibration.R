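# Fitting parameter sets to reference metrics with a hybrid genetic
# algorithm / random sampling search, plus cohort treatment experiments.

#' Reference metrics table
#'
#' The calibration targets. The three tumor-size targets (diameters 1.7, 2.4
#' and 3.2 mm at 5, 10 and 17 days post infection, from serial MRI of the
#' PDGF-driven rat model) are always present; the extended table adds the
#' cell-scale metrics printed with the experimental data (recruited fraction,
#' speed-distribution moments, persistence-time means). Rows with `NA` values
#' are placeholders awaiting data and are dropped by [objective()].
#'
#' @param extended include the cell-scale metric rows?
#' @return data.frame: `metric`, `value`, `weight`.
#' @export
reference_metrics <- function(extended = FALSE) {
  base <- data.frame(
    metric = c("diameter_5d_mm", "diameter_10d_mm", "diameter_17d_mm"),
    value = c(1.7, 2.4, 3.2),
    weight = 1,
    stringsAsFactors = FALSE
  )
  if (!extended) return(base)
  rbind(base, data.frame(
    metric = c("I_R_ratio_17d", "mean_speed_um_h", "sd_speed_um_h",
               "mean_move_time_min", "mean_stop_time_min"),
    # 80% of labeled cells recruited at 17 d => I/R = 0.25; track metrics from
    # the ex vivo assay; speed-sd placeholder (supplementary value not printed
    # in the main text)
    value = c(0.25, 23.35, NA, 42.6, 70.1),
    weight = 1, stringsAsFactors = FALSE))
}

#' Simulated calibration metrics for one parameter set
#'
#' Runs the model and extracts the metrics named in [reference_metrics()].
#' Track-derived metrics (speed moments, persistence means) are computed from
#' a virtual tracking window when `with_tracks` is `TRUE`.
#'
#' @param params a [parameter_set()].
#' @param domain a [tissue_domain()].
#' @param seed integer seed.
#' @param days days at which diameters are measured.
#' @param with_tracks also run a fine-step tracking window for cell-scale metrics?
#' @return named numeric vector of metrics.
#' @export
simulate_metrics <- function(params, domain, seed = 1L, days = c(5, 10, 17),
                             with_tracks = FALSE) {
  params$end_day <- max(days)
  run <- simulate_tumor(domain, params, record_days = days, seed = seed)
  out <- stats::setNames(
    vapply(days, function(d) run$reports[[paste0("day_", d)]]$diameter_mm,
           numeric(1)),
    paste0("diameter_", days, "d_mm"))
  last <- run$reports[[paste0("day_", max(days))]]
  out["I_R_ratio_17d"] <- last$I_R_ratio %||% NA_real_
  if (with_tracks) {
    tp <- params
    tp$dt <- 0.05
    tr <- record_tracks(domain, tp, start_day = min(2, max(days) / 2),
                        duration_h = 25, n_cells = 40L, seed = seed + 1L)
    if (!is.null(tr) && nrow(tr)) {
      ps <- suppressWarnings(population_stats(tr))
      spd <- per_cell_speed(tr)$speed_um_h
      out["mean_speed_um_h"] <- mean(spd, na.rm = TRUE)
      out["sd_speed_um_h"] <- stats::sd(spd[!is.na(spd)])
      out["mean_move_time_min"] <- ps$mean_run_h * 60
      out["mean_stop_time_min"] <- ps$mean_stop_h * 60
    }
  }
  out
}

#' Calibration objective: total weighted relative error (%)
#'
#' Per-metric error is `|sim - ref| / ref` (in %), with simulated values
#' averaged over `n_replicates` independent runs; the total is the
#' weight-averaged error over the reference metrics. Out-of-range parameters
#' are rejected before simulation; an aborted simulation scores `+Inf`.
#'
#' @param params a [parameter_set()].
#' @param reference a [reference_metrics()]-style data.frame (NA rows dropped).
#' @param domain a [tissue_domain()].
#' @param n_replicates independent runs averaged per evaluation.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param with_tracks forward to [simulate_metrics()].
#' @return total error (%) with attribute `per_metric`.
#' @export
objective <- function(params, reference, domain, n_replicates = 3, seed = 1L,
                      with_tracks = FALSE) {
  reference <- reference[!is.na(reference$value), , drop = FALSE]
  rg <- param_ranges()
  vals <- unlist(params[rg$param])
  if (any(vals < rg$lower - 1e-12 | vals > rg$upper + 1e-12))
    stop("parameter set outside admissible ranges")
  # measurement days follow the reference diameter metrics
  dm <- grep("^diameter_[0-9.]+d_mm$", reference$metric, value = TRUE)
  days <- if (length(dm))
    sort(unique(as.numeric(sub("^diameter_([0-9.]+)d_mm$", "\\1", dm))))
  else c(5, 10, 17)
  sims <- try({
    m <- sapply(seq_len(n_replicates), function(r)
      simulate_metrics(params, domain, seed = seed + r, days = days,
                       with_tracks = with_tracks)[reference$metric])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                     dimnames = list(reference$metric, NULL))
    rowMeans(m)
  }, silent = TRUE)
  if (inherits(sims, "try-error") || anyNA(sims)) {
    out <- Inf
    attr(out, "per_metric") <- stats::setNames(rep(Inf, nrow(reference)),
                                               reference$metric)
    return(out)
  }
  per <- 100 * abs(sims - reference$value) / reference$value
  total <- sum(per * reference$weight) / sum(reference$weight)
  attr(total, "per_metric") <- per
  total
}

#' Hybrid genetic-algorithm / random-sampling search
#'
#' Minimizes an arbitrary objective over a box. Each generation keeps the
#' elite, fills a `ga_fraction` of the population by tournament selection,
#' uniform crossover and per-parameter Gaussian mutation (sd = 10% of the
#' range), and draws the remainder uniformly at random from the box ("random
#' immigrants"). An archive of the best `archive_size` unique candidates and
#' a per-generation convergence trace are returned.
#'
#' @param fn objective: takes a named numeric vector (one entry per row of
#'   `bounds`), returns a scalar error (`Inf` allowed).
#' @param bounds data.frame with columns `param`, `lower`, `upper`
#'   (default [param_ranges()]).
#' @param budget total number of objective evaluations.
#' @param pop_size population per generation.
#' @param ga_fraction fraction of each generation produced by GA operators.
#' @param cx_rate uniform-crossover probability.
#' @param mut_prob per-parameter mutation probability.
#' @param mut_sd_frac mutation sd as a fraction of each parameter's range.
#' @param tournament_k tournament size.
#' @param archive_size archive capacity (best unique candidates kept).
#' @param seed integer seed.
#' @return list of class `ga_fit`: `archive` (data.frame of parameters +
#'   `error`, ascending), `trace` (best and mean error per generation),
#'   `n_eval`.
#' @export
ga_random_search <- function(fn, bounds = param_ranges(), budget = 500,
                             pop_size = 20, ga_fraction = 0.7, cx_rate = 0.9,
                             mut_prob = 0.2, mut_sd_frac = 0.1,
                             tournament_k = 2, archive_size = 300, seed = 1L) {
  stopifnot(budget >= pop_size)
  set.seed(as.integer(seed))
  d <- nrow(bounds)
  lo <- bounds$lower; hi <- bounds$upper
  rand_ind <- function() stats::runif(d, lo, hi)
  clamp <- function(v) pmin(pmax(v, lo), hi)

  evaluated <- matrix(numeric(0), ncol = d)
  errors <- numeric(0)
  n_eval <- 0L
  eval_pop <- function(P) {
    e <- apply(P, 1, function(v) fn(stats::setNames(v, bounds$param)))
    evaluated <<- rbind(evaluated, P)
    errors <<- c(errors, e)
    n_eval <<- n_eval + nrow(P)
    e
  }

  P <- t(replicate(pop_size, rand_ind()))
  E <- eval_pop(P)
  trace <- data.frame(generation = 1L, best = min(E), mean = mean(E[is.finite(E)]))

  gen <- 1L
  while (n_eval + pop_size <= budget) {
    gen <- gen + 1L
    tournament <- function() {
      k <- sample(pop_size, tournament_k)
      P[k[which.min(E[k])], ]
    }
    n_ga <- max(1L, round(ga_fraction * (pop_size - 1L)))
    n_rand <- pop_size - 1L - n_ga
    children <- matrix(0, nrow = n_ga, ncol = d)
    for (c_ in seq_len(n_ga)) {
      a <- tournament(); b <- tournament()
      child <- if (stats::runif(1) < cx_rate) {
        mask <- stats::runif(d) < 0.5
        ifelse(mask, a, b)
      } else a
      mut <- stats::runif(d) < mut_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0,
                                              mut_sd_frac * (hi - lo)[mut])
      children[c_, ] <- clamp(child)
    }
    immigrants <- if (n_rand > 0) t(replicate(n_rand, rand_ind())) else
      matrix(numeric(0), ncol = d)
    elite <- P[which.min(E), , drop = FALSE]
    newP <- rbind(children, immigrants)
    newE <- eval_pop(newP)
    P <- rbind(elite, newP)
    E <- c(min(E), newE)
    trace <- rbind(trace, data.frame(generation = gen, best = min(E),
                                     mean = mean(E[is.finite(E)])))
  }

  ord <- order(errors)
  arc <- evaluated[ord, , drop = FALSE]
  err <- errors[ord]
  dup <- duplicated(arc)
  arc <- arc[!dup, , drop = FALSE]; err <- err[!dup]
  keep <- seq_len(min(archive_size, nrow(arc)))
  archive <- as.data.frame(arc[keep, , drop = FALSE])
  names(archive) <- bounds$param
  archive$error <- err[keep]
  structure(list(archive = archive, trace = trace, n_eval = n_eval),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> %d evaluations, %d generations; best error %.3g%%\n",
              x$n_eval, nrow(x$trace), min(x$archive$error)))
  invisible(x)
}

#' Build a parameter set from an archive row
#'
#' @param row one row of a `ga_fit` archive (or any named vector/list of the
#'   16 searched parameters).
#' @param ... fixed constants forwarded to [parameter_set()] (`kappa`, `dt`, ...).
#' @return a [parameter_set()].
#' @export
params_from_archive <- function(row, ...) {
  rg <- param_ranges()
  vals <- as.list(row)[rg$param]
  do.call(parameter_set, c(vals, list(...)))
}

#' Homogeneous counterpart of a parameter set
#'
#' Same mean potential phenotype, no cell-intrinsic heterogeneity:
#' `sigma_tau = 0` and `sigma_v = 0`, everything else copied.
#'
#' @param params a [parameter_set()].
#' @return the modified parameter set.
#' @export
homogeneous_counterpart <- function(params) {
  params$sigma_tau <- 0
  params$sigma_v <- 0
  params
}

#' Cohort treatment experiment
#'
#' Runs every member of a fitted cohort under a treatment schedule and reports
#' the per-member change in tumor diameter from treatment start to end (the
#' waterfall quantity), the end-of-treatment outcome class, and pre/post
#' measured and potential proliferation statistics.
#'
#' @param archive data.frame of parameter sets (e.g. a `ga_fit` archive);
#'   non-parameter columns are ignored.
#' @param domain a [tissue_domain()].
#' @param schedule a [treatment_schedule()].
#' @param n_runs replicate runs averaged per member.
#' @param seed integer seed.
#' @param homogeneous run each member's [homogeneous_counterpart()] instead?
#' @param ... fixed constants forwarded to [parameter_set()].
#' @return data.frame, one row per member: diameters at treatment start/end,
#'   `delta_diameter_mm`, `outcome`, and phenotype summaries.
#' @export
cohort_experiment <- function(archive, domain, schedule, n_runs = 10,
                              seed = 1L, homogeneous = FALSE, ...) {
  stopifnot(nrow(archive) >= 1)
  res <- lapply(seq_len(nrow(archive)), function(k) {
    par <- params_from_archive(archive[k, ], ...)
    if (homogeneous) par <- homogeneous_counterpart(par)
    par$end_day <- schedule$end_day
    pre_d <- post_d <- p_pre <- p_post <- sd_pre <- sd_post <- numeric(n_runs)
    pp_pre <- pp_post <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      run <- simulate_tumor(domain, par, schedule = schedule,
                            record_days = c(schedule$start_day, schedule$end_day),
                            seed = seed + (k - 1L) * n_runs + r)
      a <- run$reports[[paste0("day_", schedule$start_day)]]
      b <- run$reports[[paste0("day_", schedule$end_day)]]
      pre_d[r] <- a$diameter_mm; post_d[r] <- b$diameter_mm
      p_pre[r] <- a$phenotypes$measured$p_mean %||% NA_real_
      sd_pre[r] <- a$phenotypes$measured$p_sd %||% NA_real_
      pp_pre[r] <- a$phenotypes$potential$p_mean %||% NA_real_
      p_post[r] <- b$phenotypes$measured$p_mean %||% NA_real_
      sd_post[r] <- b$phenotypes$measured$p_sd %||% NA_real_
      pp_post[r] <- b$phenotypes$potential$p_mean %||% NA_real_
    }
    data.frame(member = k,
               pre_diameter_mm = mean(pre_d), post_diameter_mm = mean(post_d),
               delta_diameter_mm = mean(post_d - pre_d),
               outcome = as.character(classify_outcome(mean(post_d))),
               p_measured_pre = mean(p_pre, na.rm = TRUE),
               p_measured_post = mean(p_post, na.rm = TRUE),
               p_sd_pre = mean(sd_pre, na.rm = TRUE),
               p_sd_post = mean(sd_post, na.rm = TRUE),
               p_potential_pre = mean(pp_pre, na.rm = TRUE),
               p_potential_post = mean(pp_post, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Go-or-grow constrained parameter pair
#'
#' Splits the phenotype space into two fixed classes for the constrained
#' fitting mode: a "grow" class that proliferates but does not migrate
#' (`v = 0`, intermitotic time fitted) and a "go" class that migrates but
#' proliferates slowly (`tau = 200` h, speed fitted). Both classes are
#' internally homogeneous.
#'
#' @param params a [parameter_set()] providing the fitted values.
#' @param enabled when `FALSE`, returns `params` unchanged (unconstrained
#'   draws).
#' @return list with elements `grow` and `go` (constrained parameter sets),
#'   or `params` when disabled.
#' @export
go_or_grow_mode <- function(params, enabled = TRUE) {
  if (!enabled) return(params)
  grow <- params; go <- params
  grow$v_mean <- 0; grow$sigma_v <- 0; grow$sigma_tau <- 0
  go$tau_mean <- 200; go$sigma_tau <- 0; go$sigma_v <- 0
  list(grow = grow, go = go)
}
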