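make_state <- function(spec, y_over = NULL, genes = NULL, dsb = 0,
                       rec = 0) {
  det <- spec$species[spec$species$partition == "deterministic", ]
  y <- setNames(det$init, det$name)
  if (!is.null(y_over)) y[names(y_over)] <- y_over
  cell_state(spec, y = y, genes = genes, dsb = dsb,
             receptors_active = rec)
}

test_that("gene activation propensity: zero input, saturation, linearity", {
  m <- build_default_model()
  det <- m$species[m$species$partition == "deterministic", ]
  zero <- setNames(rep(0, nrow(det)), det$name)
  g1 <- setNames(c(1L, 1L, 1L), m$genes$name)
  # no regulators and no basal term -> zero propensity
  m0 <- set_params(m, q0_wip1 = 0)
  st <- cell_state(m0, y = zero, genes = g1)
  expect_equal(gene_activation_propensity("g_wip1", st, m0), 0)
  # both alleles active -> zero regardless of regulators
  g2 <- setNames(c(2L, 2L, 2L), m$genes$name)
  st2 <- make_state(m, c(P53a_nuc = 5000), genes = g2)
  expect_equal(gene_activation_propensity("g_wip1", st2, m), 0)
  # doubling p53 doubles the p53-dependent component
  a0 <- gene_activation_propensity("g_wip1",
                                   make_state(m, c(P53a_nuc = 0), g1), m)
  a1 <- gene_activation_propensity("g_wip1",
                                   make_state(m, c(P53a_nuc = 1000), g1), m)
  a2 <- gene_activation_propensity("g_wip1",
                                   make_state(m, c(P53a_nuc = 2000), g1), m)
  expect_equal(a2 - a0, 2 * (a1 - a0), tolerance = 1e-12)
  # negative regulator level violates the contract
  stbad <- make_state(m, genes = g1)
  stbad$y["P53a_nuc"] <- -5
  expect_error(gene_activation_propensity("g_wip1", stbad, m), "negative")
})

test_that("gene deactivation is spontaneous and linear in active alleles", {
  m <- build_default_model()
  for (k in 0:2) {
    g <- setNames(c(k, 2L, 2L), m$genes$name)
    st_lo <- make_state(m, c(P53a_nuc = 0), genes = g)
    st_hi <- make_state(m, c(P53a_nuc = 9000), genes = g)
    a_lo <- gene_deactivation_propensity("g_wip1", st_lo, m)
    a_hi <- gene_deactivation_propensity("g_wip1", st_hi, m)
    expect_equal(a_lo, a_hi)          # regulator-independent
    expect_equal(a_lo, k * gene_deactivation_propensity(
      "g_wip1", make_state(m, genes = setNames(c(1L, 2L, 2L),
                                               m$genes$name)), m))
  }
})

test_that("Wip1 self-inhibition damps only the NF-kB activation term", {
  m <- build_default_model()
  g1 <- setNames(rep(1L, 3), m$genes$name)
  base <- make_state(m, c(NFKB_nuc = 0, WIP1 = 0, P53a_nuc = 0,
                          CREBa = 0), g1)
  hiW <- make_state(m, c(NFKB_nuc = 0, WIP1 = 1e7, P53a_nuc = 0,
                         CREBa = 0), g1)
  # without NF-kB input, Wip1 level is irrelevant
  expect_equal(gene_activation_propensity("g_wip1", base, m),
               gene_activation_propensity("g_wip1", hiW, m))
  nf <- make_state(m, c(NFKB_nuc = 3000, WIP1 = 0, P53a_nuc = 0,
                        CREBa = 0), g1)
  nfW <- make_state(m, c(NFKB_nuc = 3000, WIP1 = 1e7, P53a_nuc = 0,
                         CREBa = 0), g1)
  expect_gt(gene_activation_propensity("g_wip1", nf, m),
            gene_activation_propensity("g_wip1", nfW, m))
})

test_that("DSB channels: trivial zeros, dose window, Poisson dispersion", {
  m <- build_default_model()
  m0 <- set_params(m, dsb_background = 0)
  st0 <- make_state(m0, dsb = 0)
  ch <- dsb_channels(0, st0, m0)
  expect_equal(unname(ch), c(0, 0))
  # 10 Gy at 1 Gy/min is delivered over exactly 600 s
  pr <- make_protocol("ir_only", dose = 10)
  expect_equal(pr$ir_window, 600)
  # acute-dose DSB count is Poisson: mean k_per_gy * dose, variance ~ mean
  kpg <- 35
  spec <- make_birth_death(1, 1)$spec
  spec <- set_params(spec, bg = 0, vmax = 0)   # repair off, background off
  spec$params <- rbind(spec$params,
    data.frame(name = "kpg", value = kpg, fitted = FALSE,
               half_life = NA_real_, desc = ""))
  spec$dsb$k_per_gy <- "kpg"
  spec <- validate_model(spec)
  prot <- ddr_protocol(burn_in = 0, ir_dose = 2, ir_start = 0,
                       horizon = 240)
  cfg <- engine_config(dt = 1, save_every = 240, t_end = 240)
  counts <- vapply(1:600, function(i) {
    cfg$seed <- i
    tr <- simulate_cell(spec, prot, cfg)
    tr$dsb[length(tr$dsb)]
  }, numeric(1))
  lambda <- kpg * 2
  expect_equal(mean(counts), lambda, tolerance = 0.05)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.25)
})

test_that("TNF receptor channels: zeros, saturation, stationary fraction", {
  m <- build_default_model()
  st <- make_state(m, rec = 0)
  expect_equal(unname(tnf_receptor_channels(0, st, m)["activation"]), 0)
  total <- m$params$value[m$params$name == "n_tnfr"]
  st_full <- make_state(m, rec = total)
  expect_equal(unname(tnf_receptor_channels(10, st_full, m)["activation"]),
               0)
  # per-receptor two-state chain: stationary active fraction a/(a+d)
  ka <- m$params$value[m$params$name == "k_rec_act"] * 10
  kd <- m$params$value[m$params$name == "k_rec_deact"]
  frac <- ka / (ka + kd)
  pr <- ddr_protocol(burn_in = 0, tnf_dose = 10, tnf_start = 0,
                     tnf_duration = 3e4, horizon = 3e4)
  cfg <- engine_config(dt = 1, save_every = 10, t_end = 3e4, seed = 9)
  tr <- simulate_cell(m, pr, cfg)
  sel <- tr$times > 5000       # discard the approach to stationarity
  expect_equal(mean(tr$receptors[sel]) / total, frac, tolerance = 0.05)
})

test_that("propensities are non-negative over random reachable states", {
  m <- build_default_model()
  det <- m$species[m$species$partition == "deterministic", ]
  set.seed(7)
  for (i in 1:200) {
    y <- setNames(runif(nrow(det), 0, 2e4), det$name)
    st <- cell_state(m, y = y,
                     genes = setNames(sample(0:2, 3, TRUE), m$genes$name),
                     dsb = sample(0:500, 1),
                     receptors_active = sample(0:300, 1))
    for (g in m$genes$name) {
      expect_gte(gene_activation_propensity(g, st, m), 0)
      expect_gte(gene_deactivation_propensity(g, st, m), 0)
    }
    expect_true(all(dsb_channels(runif(1, 0, 0.2), st, m) >= 0))
    expect_true(all(tnf_receptor_channels(runif(1, 0, 20), st, m) >= 0))
  }
})

test_that("allele occupancy matches the 3-state chain closed form", {
  # long-run occupancy of the toggle fixture vs the binomial solution
  a <- 2e-3; d <- 3e-3
  toy <- make_gene_toggle(a, d)
  pr <- ddr_protocol(burn_in = 0, horizon = 4e5)
  cfg <- engine_config(dt = 5, save_every = 50, t_end = 4e5, seed = 11)
  tr <- simulate_cell(toy$spec, pr, cfg, genes0 = 0L)
  g <- tr$G[tr$times > 2e4, 1]
  emp <- tabulate(g + 1L, 3) / length(g)
  expect_equal(emp, unname(toggle_stationary(a, d)), tolerance = 0.08)
  # chi-squared goodness of fit at alpha = 0.01 (time samples thinned to
  # roughly independent draws: switching timescale 1/(a+d) = 200 s)
  thin <- g[seq(1, length(g), by = 10)]
  obs <- tabulate(thin + 1L, 3)
  p <- toggle_stationary(a, d)
  stat <- sum((obs - sum(obs) * p)^2 / (sum(obs) * p))
  expect_gt(pchisq(stat, df = 2, lower.tail = FALSE), 0.01)
})

test_that("direct Gillespie sampler follows the exponential/categorical law", {
  set.seed(13)
  a <- 0.05
  draws <- vapply(1:3e4, function(i) gillespie_next_event(a)$dt, numeric(1))
  expect_equal(mean(draws), 1 / a, tolerance = 0.02)
  picks <- vapply(1:2e4, function(i)
    gillespie_next_event(c(a, 3 * a))$channel, integer(1))
  expect_equal(mean(picks == 1), 0.25, tolerance = 0.04)
  expect_equal(gillespie_next_event(c(0, 0))$dt, Inf)
  expect_error(gillespie_next_event(c(-1, 2)), "non-negative")
})
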