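tiny_domain <- function() {
  make_synthetic_brain(2.5, 2.5, tract = list(y_mm = 1.25, thickness_mm = 0.4),
                       px_size = 25, seed = 1)
}

tiny_params <- function(v, ...) {
  do.call(parameter_set,
          c(as.list(v), list(kappa = 15, dt = 0.5, end_day = 4,
                             max_cells = 2e4, range_check = "none", ...)))
}

test_that("the objective is the weighted mean relative error over metrics", {
  dom <- tiny_domain()
  par <- tiny_params(c(tau_mean = 35, sigma_tau = 10, v_mean = 15, sigma_v = 5,
                       p0 = 300, D_p = 2e-4, r_d = 0.2, r_s = 150, r_c = 0.05,
                       K_p = 40, K_m = 40, beta_p = 0.5, beta_m = 0.5,
                       p_a = 15, rho_R = 1.5, sigma_theta = 20))
  days <- c(2, 3, 4)
  sim <- simulate_metrics(par, dom, seed = 8, days = days)

  # reference equal to one replicate's own metrics: zero error
  ref <- data.frame(metric = paste0("diameter_", days, "d_mm"),
                    value = unname(sim[paste0("diameter_", days, "d_mm")]),
                    weight = 1)
  par$end_day <- 4
  e0 <- objective(par, ref, dom, n_replicates = 1, seed = 7)  # seed + 1 = 8
  expect_equal(as.numeric(e0), 0, tolerance = 1e-9)

  # inflating one reference by 10% makes the size-mode error (10+0+0)/3
  ref2 <- ref
  ref2$value[1] <- ref$value[1] / 1.1
  e1 <- objective(par, ref2, dom, n_replicates = 1, seed = 7)
  expect_equal(as.numeric(e1), 100 * (1 - 1 / 1.1) * 1.1 / 3, tolerance = 1e-6)
  per <- attr(e1, "per_metric")
  expect_equal(unname(per[2:3]), c(0, 0), tolerance = 1e-9)

  # NA reference rows (placeholders) are dropped
  ref3 <- rbind(ref, data.frame(metric = "unmeasured", value = NA, weight = 1))
  expect_equal(as.numeric(objective(par, ref3, dom, 1, seed = 7)), 0,
               tolerance = 1e-9)

  # out-of-range parameters are rejected before any simulation
  bad <- par; bad$tau_mean <- 500
  expect_error(objective(bad, ref, dom, 1, 1), "outside admissible")
})

test_that("the hybrid GA beats random sampling on a surrogate objective", {
  # cheap 16-d quadratic bowl over the real parameter box
  rg <- param_ranges()
  target <- (rg$lower + rg$upper) / 2 + 0.17 * (rg$upper - rg$lower)
  bowl <- function(v) sum(((v - target) / (rg$upper - rg$lower))^2)

  fit <- ga_random_search(bowl, budget = 400, pop_size = 20, seed = 5)
  # elitism: per-generation best is non-increasing
  expect_true(all(diff(fit$trace$best) <= 1e-12))
  # archive sorted ascending, capped, unique
  expect_true(all(diff(fit$archive$error) >= 0))
  expect_lte(nrow(fit$archive), 300)
  expect_false(any(duplicated(fit$archive[param_ranges()$param])))

  # determinism
  fit2 <- ga_random_search(bowl, budget = 400, pop_size = 20, seed = 5)
  expect_identical(fit$archive, fit2$archive)

  # degenerate budget: one generation of pure random sampling
  fit3 <- ga_random_search(bowl, budget = 20, pop_size = 20, seed = 2)
  expect_equal(fit3$n_eval, 20)
  expect_equal(nrow(fit3$trace), 1)

  # the hybrid search beats equal-budget pure random sampling in >= 80% of
  # 20 paired trials
  wins <- 0
  for (k in 1:20) {
    ga_best <- min(ga_random_search(bowl, budget = 300, pop_size = 20,
                                    seed = 100 + k)$archive$error)
    set.seed(200 + k)
    P <- sapply(seq_len(nrow(rg)), function(j)
      stats::runif(300, rg$lower[j], rg$upper[j]))
    rnd_best <- min(apply(P, 1, bowl))
    if (ga_best < rnd_best) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("a scaled search recovers metrics generated by a known parameter set", {
  dom <- tiny_domain()
  truth <- c(rho_R = 1.5, sigma_theta = 20, p0 = 300, D_p = 2e-4, r_d = 0.2,
             r_s = 150, r_c = 0.05, p_a = 15, K_p = 40, K_m = 40,
             beta_p = 0.5, beta_m = 0.5, tau_mean = 35, sigma_tau = 10,
             v_mean = 15, sigma_v = 5)
  days <- c(2, 3, 4)
  ref_vals <- simulate_metrics(tiny_params(truth), dom, seed = 51, days = days)
  ref <- data.frame(metric = paste0("diameter_", days, "d_mm"),
                    value = unname(ref_vals[paste0("diameter_", days, "d_mm")]),
                    weight = 1)

  fn <- function(v) {
    par <- tiny_params(v)
    tryCatch(as.numeric(objective(par, ref, dom, n_replicates = 1, seed = 60)),
             error = function(e) Inf)
  }
  fit <- ga_random_search(fn, budget = 60, pop_size = 10, seed = 31)
  # the best fit reproduces the reference sizes within 10%
  expect_lt(min(fit$archive$error), 10)
  # identifiability caveat: several distinct sets fit the sizes comparably
  expect_gte(sum(fit$archive$error < 10), 5)
})

test_that("cohort experiments report growth, treatment response and counterparts", {
  dom <- tiny_domain()
  arch <- rbind(
    data.frame(rho_R = 1.5, sigma_theta = 20, p0 = 300, D_p = 2e-4, r_d = 0.2,
               r_s = 150, r_c = 0.05, p_a = 15, K_p = 40, K_m = 40,
               beta_p = 0.5, beta_m = 0.5, tau_mean = 35, sigma_tau = 10,
               v_mean = 15, sigma_v = 5),
    data.frame(rho_R = 1, sigma_theta = 10, p0 = 250, D_p = 1e-4, r_d = 0.1,
               r_s = 120, r_c = 0.03, p_a = 20, K_p = 60, K_m = 60,
               beta_p = 0.4, beta_m = 0.4, tau_mean = 30, sigma_tau = 20,
               v_mean = 20, sigma_v = 10))

  # untreated growth: diameter increases for every member
  none <- treatment_schedule("none", start_day = 2, end_day = 4)
  res <- cohort_experiment(arch, dom, none, n_runs = 1, seed = 3,
                           kappa = 15, dt = 0.5, max_cells = 2e4,
                           range_check = "none")
  expect_equal(nrow(res), 2)
  expect_true(all(res$delta_diameter_mm > 0))

  # AM alone kills nothing: no member shrinks
  am <- treatment_schedule("AM", start_day = 2, end_day = 4)
  res_am <- cohort_experiment(arch, dom, am, n_runs = 1, seed = 3,
                              kappa = 15, dt = 0.5, max_cells = 2e4,
                              range_check = "none")
  expect_true(all(res_am$delta_diameter_mm >= 0))

  # homogeneous counterparts zero the spreads and nothing else
  hpar <- homogeneous_counterpart(params_from_archive(arch[2, ],
                                                      range_check = "none"))
  expect_equal(hpar$sigma_tau, 0)
  expect_equal(hpar$sigma_v, 0)
  expect_equal(hpar$tau_mean, 30)
  expect_equal(hpar$v_mean, 20)
})

test_that("go-or-grow mode produces the constrained class pair", {
  par <- quick_params()
  gg <- go_or_grow_mode(par)
  expect_equal(gg$grow$v_mean, 0)     # grow class does not migrate
  expect_equal(gg$go$tau_mean, 200)   # go class proliferates slowly
  expect_equal(gg$grow$sigma_tau, 0)
  expect_equal(gg$go$sigma_v, 0)
  # mode off: unchanged, unconstrained draws
  expect_identical(go_or_grow_mode(par, enabled = FALSE), par)
})
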