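test_that("PDGF response matches the Hill forms for both lineages", {
  # recruited cells are inactive at zero PDGF
  expect_equal(gamma_response(0, "RECRUITED", K = 50, beta = 0.5, p_a = 10), 0)
  # half-max identity for infected cells without autocrine boost
  expect_equal(gamma_response(50, "INFECTED", K = 50, beta = 1, p_a = 0), 0.5)
  # direct evaluation with the autocrine boost
  expect_equal(gamma_response(40, "INFECTED", K = 50, beta = 1, p_a = 10), 0.5)
  # recruited at C = K with beta = 0.1
  expect_equal(gamma_response(50, "RECRUITED", K = 50, beta = 0.1, p_a = 0),
               1 / 1.1)
})

test_that("gamma is bounded, monotone, and recruited cells beat the bare Hill curve", {
  C <- c(0, 10^seq(-4, 4, length.out = 50))
  for (lin in names(LINEAGE)) {
    g <- gamma_response(C, rep(lin, length(C)), K = 80, beta = 0.3, p_a = 5)
    expect_true(all(g >= 0 & g < 1))
    expect_true(all(diff(g) > 0))
  }
  # decreased activation barrier: beta < 1 lifts the recruited response above
  # the unmodified Hill curve at every positive concentration
  Cp <- C[C > 0]
  g_rec <- gamma_response(Cp, rep("RECRUITED", length(Cp)), K = 80, beta = 0.3,
                          p_a = 0)
  expect_true(all(g_rec > Cp / (Cp + 80)))
})

test_that("observed phenotype scales the potentials by the response", {
  par <- quick_params()
  # saturation: gamma -> 1 gives (1/tau, v)
  ob <- observed_phenotype(50, 30, C_PP = 1e9, LINEAGE["RECRUITED"], par)
  expect_equal(ob$p, 1 / 50, tolerance = 1e-6)
  expect_equal(ob$m, 30, tolerance = 1e-6)
  # zero PDGF, recruited: fully off
  ob0 <- observed_phenotype(50, 30, 0, LINEAGE["RECRUITED"], par)
  expect_equal(c(ob0$p, ob0$m), c(0, 0))
  # gamma = 0.5 at tau = 50 h gives p = 0.01 per hour
  par2 <- quick_params(); par2$K_p <- 50; par2$beta_p <- 1; par2$p_a <- 0
  ob5 <- observed_phenotype(50, 30, 50, LINEAGE["INFECTED"], par2)
  expect_equal(ob5$p, 0.01)
})

test_that("cycle advance freezes under crowding and divides on schedule", {
  # over capacity: quiescent, progress frozen exactly where it left off
  a <- advance_cycle(cycle = 0.4, p = 0.02, dt = 1, local_count = 101,
                     capacity = 100)
  expect_true(a$quiescent)
  expect_equal(a$cycle, 0.4)
  expect_false(a$divide)

  # p = 0: progress never accumulates
  b <- advance_cycle(0.3, 0, 1, 10, 100)
  expect_equal(b$cycle, 0.3)
  expect_false(b$divide)

  # progress crossing 1 emits a division and resets
  c_ <- advance_cycle(0.995, 0.01, 1, 10, 100)
  expect_true(c_$divide)
  expect_equal(c_$cycle, 0)
})

test_that("daughters are placed one radius away at uniform angles and inherit exactly", {
  dom <- gray_domain(2)
  set.seed(2)
  n <- 4000
  pos <- place_daughters(dom, rep(1000, n), rep(1000, n))
  d <- sqrt((pos$x - 1000)^2 + (pos$y - 1000)^2)
  expect_equal(d, rep(12.5, n), tolerance = 1e-9)
  ang <- atan2(pos$y - 1000, pos$x - 1000)
  cnt <- table(cut(ang, breaks = seq(-pi, pi, length.out = 13)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)

  # daughters near a border never land in EMPTY space
  domv <- make_synthetic_brain(1, 1, px_size = 20, seed = 2,
                               ventricles = list(list(x_mm = 0.5, y_mm = 0.5,
                                                      r_mm = 0.2)))
  px <- rep(500 - 0.2 * 1000 - 2, 500)  # 2 um outside the ventricle wall
  pos2 <- place_daughters(domv, px, rep(500, 500))
  expect_true(all(pixel_class(domv, pos2$x, pos2$y) != TISSUE["EMPTY"]))

  # inheritance is exact along lineages in a full simulation
  run <- simulate_tumor(gray_domain(2), quick_params(end_day = 2), seed = 11)
  df <- cells_df(run$final$pop)
  kids <- df[df$parent_id > 0, ]
  parents <- df[match(kids$parent_id, df$id), ]
  ok <- !is.na(parents$id)
  expect_gt(sum(ok), 10)
  expect_equal(kids$tau_h[ok], parents$tau_h[ok])
  expect_equal(kids$v_um_per_h[ok], parents$v_um_per_h[ok])
})

test_that("recruitable activation uses a strict threshold", {
  expect_false(maybe_activate(0))
  expect_true(maybe_activate(6e-4))
  expect_false(maybe_activate(5e-4))  # boundary stays inactive
})

test_that("initial populations have the right counts, spreads and seeding density", {
  dom <- gray_domain(3)
  par <- quick_params(sigma_tau = 0, sigma_v = 0, rho_R = 2, kappa = 100)
  init <- init_population(dom, par, seed = 3)
  df <- cells_df(init$pop)
  expect_equal(sum(df$lineage == "INFECTED"), 100)
  expect_equal(sum(df$lineage == "RECRUITED"), 100)
  # homogeneous model: all cells share the mean phenotype
  expect_equal(unique(df$tau_h), par$tau_mean)
  expect_equal(unique(df$v_um_per_h), par$v_mean)
  # all inside the injection disc
  site <- c(dom$width_um, dom$height_um) / 2
  expect_true(all((df$x_um - site[1])^2 + (df$y_um - site[2])^2 <=
                    par$injection_radius^2 + 1e-6))

  # recruitable seeding: Poisson with mean rho_R% of capacity per node
  lam <- 0.02 * 100
  n_nodes <- dom$density$nx * dom$density$ny
  tot <- length(init$recruitable$x)
  expect_equal(tot / n_nodes, lam, tolerance = 4 * sqrt(lam * n_nodes) / (lam * n_nodes))
  # dispersion consistent with Poisson (variance ~ mean)
  node <- nearest_density_node(dom, init$recruitable$x, init$recruitable$y)
  cnt <- tabulate(node, n_nodes)
  expect_equal(stats::var(cnt) / mean(cnt), 1, tolerance = 0.15)

  expect_error(init_population(dom, quick_params(injection_site = c(-100, -100))),
               "outside tissue")
})

test_that("phenotype draws respect the truncation bounds", {
  set.seed(5)
  par <- quick_params(tau_mean = 20, sigma_tau = 40, v_mean = 5, sigma_v = 40,
                      range_check = "none")
  init <- init_population(gray_domain(2), par)
  df <- cells_df(init$pop)
  expect_true(all(df$tau_h >= 5))
  expect_true(all(df$v_um_per_h >= 0 & df$v_um_per_h <= 100))
})
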