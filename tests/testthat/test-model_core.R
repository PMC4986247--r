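test_that("default model covers the declared inventory and compartments", {
  m <- build_default_model()
  expect_setequal(unique(m$species$compartment),
                  c("extracellular", "cytoplasm", "nucleus"))
  needed <- c("ATM", "ATMa", "MRN", "CHK2", "P53_cyt", "P53_nuc",
              "P53a_nuc", "MDM2_cyt", "MDM2_nuc", "MDM2pp_nuc",
              "WIP1_mRNA", "WIP1", "MIR16", "KSRP", "CREB", "NFKB_cyt",
              "NFKB_nuc", "IKB", "IKKn", "A20", "P21_mRNA", "P21",
              "BAX_mRNA", "BAX", "DSB", "TNFR")
  expect_true(all(needed %in% m$species$name))
  expect_setequal(m$genes$name, c("g_wip1", "g_chk2", "g_atm"))
})

test_that("removing a parameter is a load error naming the symbol", {
  m <- build_default_model()
  keep <- m$params$name != "k_wip_p53"
  expect_error(
    ddr_model(m$species, m$params[keep, ], m$reactions, m$genes,
              m$gene_regs, m$dsb, m$receptors),
    "k_wip_p53")
})

test_that("an unresolved species symbol is a load error naming it", {
  m <- build_default_model()
  bad <- rbind(m$reactions,
               ddr_reaction("bogus", "d_p53", src = "NOT_A_SPECIES",
                            f1 = "lin:NOT_A_SPECIES"))
  expect_error(
    ddr_model(m$species, m$params, bad, m$genes, m$gene_regs, m$dsb,
              m$receptors),
    "NOT_A_SPECIES")
})

test_that("degradation rates equal ln2 / half-life to 1e-12 relative", {
  m <- build_default_model()
  hl <- m$params[!is.na(m$params$half_life), ]
  expect_gt(nrow(hl), 10)
  for (i in seq_len(nrow(hl)))
    expect_equal(hl$value[i], log(2) / hl$half_life[i],
                 tolerance = 1e-12)
})

test_that("a non-negative resting fixed point exists and is locatable", {
  m <- build_default_model()
  rest <- find_rest(m)
  expect_true(all(rest$y >= 0))
  expect_true(all(rest$genes >= 0 & rest$genes <= 2))
  expect_lt(rest$max_abs_deriv, 1e-4)
})

test_that("empty cell produces only constitutive source fluxes", {
  m <- build_default_model()
  det <- m$species[m$species$partition == "deterministic", ]
  st <- cell_state(m, y = setNames(rep(0, nrow(det)), det$name),
                   genes = setNames(rep(0L, 3), m$genes$name))
  dy <- rhs(st, m)
  expect_true(all(dy >= 0))
  # species with a constant synthesis term gain mass; all other derivatives
  # are exactly zero
  const_src <- m$reactions$dst[is.na(m$reactions$f1) &
                                 is.na(m$reactions$src)]
  expect_true(all(dy[setdiff(names(dy), const_src)] == 0))
  expect_true(all(dy[unique(const_src)] > 0))
})

test_that("transcription flux is linear in allele count", {
  m <- build_default_model()
  rest <- find_rest(m)
  g0 <- setNames(rep(1L, 3), m$genes$name)
  dy <- list()
  for (k in 0:2) {
    g <- g0; g["g_wip1"] <- k
    dy[[k + 1]] <- rhs(cell_state(m, y = rest$y, genes = g), m)
  }
  d01 <- dy[[2]]["WIP1_mRNA"] - dy[[1]]["WIP1_mRNA"]
  d12 <- dy[[3]]["WIP1_mRNA"] - dy[[2]]["WIP1_mRNA"]
  expect_gt(d01, 0)
  expect_equal(unname(d01), unname(d12), tolerance = 1e-12)
})

test_that("transport terms cancel over compartments for random states", {
  m <- build_default_model()
  det <- m$species[m$species$partition == "deterministic", ]
  set.seed(42)
  shuttled <- list(p53 = c("P53_cyt", "P53_nuc"),
                   mdm2 = c("MDM2_cyt", "MDM2_nuc"),
                   nfkb = c("NFKB_cyt", "NFKB_nuc"))
  for (rep in 1:100) {
    y <- setNames(runif(nrow(det), 0, 5000), det$name)
    st <- cell_state(m, y = y, genes = setNames(sample(0:2, 3, TRUE),
                                                m$genes$name),
                     dsb = sample(0:300, 1))
    tt <- transport_terms(st, m)
    for (pair in shuttled)
      expect_equal(sum(tt[pair]), 0, tolerance = 1e-9)
  }
})

test_that("with zero transport rates the rhs is compartment-local", {
  m <- build_default_model()
  m0 <- set_params(m, k_p53_imp = 0, k_md_imp = 0, k_nf_imp = 0,
                   k_nf_exp = 0)
  rest <- find_rest(m)
  st <- cell_state(m0, y = rest$y, dsb = 50)
  local <- m0
  local$reactions <- local$reactions[!local$reactions$transport, ]
  expect_equal(rhs(st, local), rhs(st, m0), tolerance = 1e-12)
})

test_that("negative species levels violate the rhs contract", {
  m <- build_default_model()
  rest <- find_rest(m)
  y <- rest$y; y[1] <- -1
  st <- structure(list(t = 0, y = y,
                       genes = setNames(rep(2L, 3), m$genes$name),
                       dsb = 0, receptors_active = 0),
                  class = "cell_state")
  expect_error(rhs(st, m), "non-negative")
})

test_that("pure exponential decay halves in ln2/k within 1%", {
  toy <- make_birth_death(k_syn = 1, k_deg = 1e-3)
  spec <- set_params(toy$spec, k_syn = 0, bg = 0)
  pr <- ddr_protocol(burn_in = 0, horizon = log(2) / 1e-3)
  cfg <- engine_config(dt = 0.1, save_every = 10,
                       t_end = log(2) / 1e-3, seed = 1)
  tr <- simulate_cell(spec, pr, cfg, init = c(X = 1000),
                      stochastic = FALSE)
  final <- tr$Y[nrow(tr$Y), "X"]
  expect_equal(unname(final), 500, tolerance = 0.01)
})

test_that("model YAML serialization round-trips losslessly", {
  m <- build_default_model()
  path <- tempfile(fileext = ".yaml")
  model_to_yaml(m, path)
  m2 <- model_from_yaml(path)
  expect_equal(m2$params$value, m$params$value)
  expect_equal(m2$species, m$species)
  expect_equal(m2$reactions$rate, m$reactions$rate)
  rest <- find_rest(m)
  st1 <- cell_state(m, y = rest$y, dsb = 100)
  st2 <- cell_state(m2, y = rest$y, dsb = 100)
  expect_equal(rhs(st2, m2), rhs(st1, m))
})
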