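# Toy fixtures with known analytic behaviour.  They exercise the same
# declarative-model machinery and engine as the full network, but never
# depend on the default model definition.

toy_model <- function(name, spec, analytic) {
  structure(list(name = name, spec = spec, analytic = analytic),
            class = "toy_model")
}

toy_params <- function(...) {
  kv <- list(...)
  data.frame(name = names(kv), value = unlist(kv), fitted = FALSE,
             half_life = NA_real_, desc = "", stringsAsFactors = FALSE)
}

no_genes <- data.frame(name = character(), q0 = character(),
                       deact = character(), stringsAsFactors = FALSE)
no_regs <- data.frame(gene = character(), species = character(),
                      weight = character(), inh_species = character(),
                      inh_K = character(), stringsAsFactors = FALSE)

#' Birth-death toy model
#'
#' One continuous species `X` (synthesis `k_syn`, first-order decay `k_deg`)
#' and one stochastic counter with the same rates (realised through the
#' discrete damage channel with a very large half-saturation constant, so
#' removal is first order to within `count / 1e9`).  The stationary
#' distribution of the counter is Poisson with mean `k_syn / k_deg`; the
#' continuous species has the same fixed point.
#'
#' @param k_syn birth rate (molecules/s).
#' @param k_deg death rate (1/s).
#' @return a `toy_model`.
#' @export
make_birth_death <- function(k_syn, k_deg) {
  stopifnot(k_syn > 0, k_deg > 0)
  km_big <- 1e9
  spec <- ddr_model(
    species = ddr_species("X", "cytoplasm", "protein", init = 0),
    params = toy_params(k_syn = k_syn, k_deg = k_deg,
                        bg = k_syn, vmax = k_deg * km_big, km = km_big,
                        zero = 0, one = 1),
    reactions = rbind(
      ddr_reaction("x_syn", "k_syn", dst = "X"),
      ddr_reaction("x_deg", "k_deg", src = "X", f1 = "lin:X")),
    genes = no_genes, gene_regs = no_regs,
    dsb = list(k_per_gy = "zero", background = "bg", vmax = "vmax",
               km = "km"),
    receptors = list(total = "zero", k_act = "zero", k_deact = "zero"),
    name = "birth_death")
  toy_model("birth_death", spec,
            analytic = list(mean = k_syn / k_deg, var = k_syn / k_deg,
                            pois_lambda = k_syn / k_deg))
}

#' Two-allele gene toggle toy model
#'
#' A single gene with constant activation propensity `a` per inactive allele
#' and deactivation `d` per active allele, driving a transcript `X`.
#' Alleles switch independently, so the stationary occupancy of the states
#' {0, 1, 2} is binomial with per-allele on-probability `a / (a + d)`.
#'
#' @param a activation propensity per inactive allele (1/s).
#' @param d deactivation propensity per active allele (1/s).
#' @return a `toy_model`.
#' @export
make_gene_toggle <- function(a, d) {
  stopifnot(a > 0, d > 0)
  pi_on <- a / (a + d)
  spec <- ddr_model(
    species = ddr_species("X", "nucleus", "mRNA", init = 0),
    params = toy_params(q_act = a, q_deact = d, s_x = 0.1, d_x = 1e-3,
                        zero = 0),
    reactions = rbind(
      ddr_reaction("x_syn", "s_x", dst = "X", f1 = "gene:g"),
      ddr_reaction("x_deg", "d_x", src = "X", f1 = "lin:X")),
    genes = data.frame(name = "g", q0 = "q_act", deact = "q_deact",
                       stringsAsFactors = FALSE),
    gene_regs = no_regs,
    dsb = list(k_per_gy = "zero", background = "zero", vmax = "zero",
               km = "zero"),
    receptors = list(total = "zero", k_act = "zero", k_deact = "zero"),
    name = "gene_toggle")
  toy_model("gene_toggle", spec,
            analytic = list(
              occupancy = stats::setNames(stats::dbinom(0:2, 2, pi_on),
                                          c("0", "1", "2")),
              mean_alleles = 2 * pi_on))
}

#' Synthetic decay time course
#'
#' Exponential decay sampled at a cycloheximide/actinomycin-D-style chase
#' cadence (15 min to 8 h) with multiplicative log-normal noise.
#'
#' @param t_half half-life (hours).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_points number of samples.
#' @param seed integer seed.
#' @param level0 level at time 0.
#' @return list with `times` (hours) and `levels`.
#' @export
make_decay_series <- function(t_half, noise_cv = 0, n_points = 8,
                              seed = 1, level0 = 100) {
  stopifnot(t_half > 0, noise_cv >= 0, n_points >= 3)
  times <- exp(seq(log(0.25), log(8), length.out = n_points))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- if (noise_cv > 0)
    exp(stats::rnorm(n_points, -sdlog^2 / 2, sdlog)) else 1
  list(times = times, levels = level0 * 2^(-times / t_half) * noise)
}

#' Fast-scaled damage-response cascade
#'
#' A compact, 60-fold-accelerated caricature of the full network used for
#' population-level property tests: a damage-driven signal (named
#' `P53a_nuc` so the standard fate machinery applies), a gene-switched
#' antagonist (`WIP1`) that silences the signal, and the two fate readouts
#' `P21` and `BAX`.  It is deliberately NOT quantitatively faithful to the
#' full model; it exists so that dose-response and genotype-ordering
#' properties can be checked in seconds.
#'
#' @param wip1_expression expression scale of the antagonist (0.25 mimics
#'   the knockdown genotype).
#' @return a `toy_model`; `analytic$rest` gives the exact no-damage fixed
#'   point.
#' @export
make_fast_ddr <- function(wip1_expression = 1) {
  stopifnot(wip1_expression >= 0, wip1_expression <= 1)
  q0 <- 6e-4; dg <- 6e-3; s_w <- 2 * wip1_expression; d_w <- 1.9e-3
  g_mean <- 2 * q0 / (q0 + dg)
  rest <- c(P53a_nuc = 0, WIP1 = s_w * g_mean / d_w,
            P21 = 0.04 / 3.85e-3, BAX = 0.02 / 2.9e-3)
  spec <- ddr_model(
    species = rbind(
      ddr_species("P53a_nuc", "nucleus", "protein_phospho", init = 0),
      ddr_species("WIP1", "nucleus", "protein",
                  init = round(rest[["WIP1"]])),
      ddr_species("P21", "nucleus", "protein", init = 10),
      ddr_species("BAX", "cytoplasm", "protein", init = 7)),
    params = toy_params(
      s_sig = 10, K_sig = 70, d_sig = 1.4e-3, k_wsig = 2e-3, Km_wsig = 500,
      s_w = s_w, d_w = d_w,
      s_p0 = 0.04, s_p = 2e-3, d_p = 3.85e-3,
      s_b0 = 0.02, s_b = 1e-3, d_b = 2.9e-3,
      q0_w = q0, d_g_w = dg, q_sig_w = 2e-5,
      k_per_gy = 35, bg = 1.8e-4, vmax = 0.0438, km = 25, zero = 0),
    reactions = rbind(
      ddr_reaction("sig_syn", "s_sig", dst = "P53a_nuc",
                   f1 = "dsbmm:K_sig"),
      ddr_reaction("sig_deg", "d_sig", src = "P53a_nuc",
                   f1 = "lin:P53a_nuc"),
      ddr_reaction("sig_off_w", "k_wsig", src = "P53a_nuc",
                   f1 = "lin:WIP1", f2 = "mm:P53a_nuc:Km_wsig"),
      ddr_reaction("w_syn", "s_w", dst = "WIP1", f1 = "gene:g_wip1"),
      ddr_reaction("w_deg", "d_w", src = "WIP1", f1 = "lin:WIP1"),
      ddr_reaction("p_syn0", "s_p0", dst = "P21"),
      ddr_reaction("p_syn", "s_p", dst = "P21", f1 = "lin:P53a_nuc"),
      ddr_reaction("p_deg", "d_p", src = "P21", f1 = "lin:P21"),
      ddr_reaction("b_syn0", "s_b0", dst = "BAX"),
      ddr_reaction("b_syn", "s_b", dst = "BAX", f1 = "lin:P53a_nuc"),
      ddr_reaction("b_deg", "d_b", src = "BAX", f1 = "lin:BAX")),
    genes = data.frame(name = "g_wip1", q0 = "q0_w", deact = "d_g_w",
                       stringsAsFactors = FALSE),
    gene_regs = data.frame(gene = "g_wip1", species = "P53a_nuc",
                           weight = "q_sig_w",
                           inh_species = NA_character_,
                           inh_K = NA_character_, stringsAsFactors = FALSE),
    dsb = list(k_per_gy = "k_per_gy", background = "bg", vmax = "vmax",
               km = "km"),
    receptors = list(total = "zero", k_act = "zero", k_deact = "zero"),
    name = sprintf("fast_ddr_%g", wip1_expression))
  toy_model("fast_ddr", spec, analytic = list(rest = rest))
}
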