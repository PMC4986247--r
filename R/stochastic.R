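# Stochastic partition: gene allele switching, DSB appearance/repair,
# TNF receptor turnover.  Each channel is a state-dependent propensity (1/s)
# plus a discrete effect; the hybrid engine samples them with the direct
# Gillespie method.

#' Gene activation propensity
#'
#' Propensity (1/s) for switching one inactive allele of `gene` on.  The rate
#' is `(q0 + sum_i w_i * level_i * [inh_i])` per inactive allele, where each
#' regulator contribution may carry a multiplicative inhibition factor
#' `K/(K + inhibitor level)` (used for Wip1's self-limited NF-kB-dependent
#' activation and for the p53-dependent damping of Chk2 activation).
#'
#' @param gene gene name (a row of `spec$genes`).
#' @param state a `cell_state`.
#' @param spec a `ddr_model`.
#' @return non-negative rate in 1/s.
#' @export
gene_activation_propensity <- function(gene, state, spec) {
  gi <- match(gene, spec$genes$name)
  if (is.na(gi)) stop("unknown gene '", gene, "'", call. = FALSE)
  inactive <- 2L - state$genes[[gene]]
  if (inactive <= 0L) return(0)
  if (any(state$y < 0)) stop("negative regulator level", call. = FALSE)
  a <- param_value(spec, spec$genes$q0[gi])
  regs <- spec$gene_regs[spec$gene_regs$gene == gene, , drop = FALSE]
  for (i in seq_len(nrow(regs))) {
    gr <- regs[i, ]
    contrib <- param_value(spec, gr$weight) * unname(state$y[gr$species])
    if (!is.na(gr$inh_species)) {
      K <- param_value(spec, gr$inh_K)
      contrib <- contrib * K / (K + unname(state$y[gr$inh_species]))
    }
    a <- a + contrib
  }
  a * inactive
}

#' Gene deactivation propensity
#'
#' Deactivation is spontaneous (regulator-independent):
#' `deact_rate * active alleles`.
#'
#' @inheritParams gene_activation_propensity
#' @return non-negative rate in 1/s.
#' @export
gene_deactivation_propensity <- function(gene, state, spec) {
  gi <- match(gene, spec$genes$name)
  if (is.na(gi)) stop("unknown gene '", gene, "'", call. = FALSE)
  param_value(spec, spec$genes$deact[gi]) * state$genes[[gene]]
}

#' DSB induction and repair propensities
#'
#' Induction fires at `k_per_gy * dose_rate + background` (the background term
#' produces the occasional spontaneous damage seen in unirradiated cells);
#' repair fires at the saturating repair-capacity rate
#' `vmax * dsb / (km + dsb)`.  Each firing changes the DSB count by +1 or -1.
#'
#' @param dose_rate instantaneous dose rate in Gy/s (0 outside the delivery
#'   window).
#' @param state a `cell_state`.
#' @param spec a `ddr_model`.
#' @return named vector `c(induction =, repair =)` in 1/s.
#' @export
dsb_channels <- function(dose_rate, state, spec) {
  stopifnot(dose_rate >= 0)
  ind <- param_value(spec, spec$dsb$k_per_gy) * dose_rate +
    param_value(spec, spec$dsb$background)
  vmax <- param_value(spec, spec$dsb$vmax)
  km <- param_value(spec, spec$dsb$km)
  rep <- if (state$dsb > 0) vmax * state$dsb / (km + state$dsb) else 0
  c(induction = ind, repair = rep)
}

#' TNF receptor activation and deactivation propensities
#'
#' Activation fires at `k_act * tnf_level * inactive receptors`; deactivation
#' at `k_deact * active receptors`.  Active receptors feed the IKK
#' activation term of the continuous partition.
#'
#' @param tnf_level extracellular TNF-alpha concentration (ng/ml).
#' @param state a `cell_state`.
#' @param spec a `ddr_model`.
#' @return named vector `c(activation =, deactivation =)` in 1/s.
#' @export
tnf_receptor_channels <- function(tnf_level, state, spec) {
  stopifnot(tnf_level >= 0)
  total <- param_value(spec, spec$receptors$total)
  inact <- max(0, total - state$receptors_active)
  c(activation = param_value(spec, spec$receptors$k_act) * tnf_level * inact,
    deactivation = param_value(spec, spec$receptors$k_deact) *
      state$receptors_active)
}

#' Sample the next stochastic event (direct Gillespie)
#'
#' Draws the waiting time from an exponential with the summed propensity and
#' picks the channel with probability proportional to its propensity.  A zero
#' total propensity returns an infinite waiting time.
#'
#' @param propensities non-negative numeric vector.
#' @return list with `dt` (seconds) and `channel` (index, `NA` when no event
#'   can fire).
#' @export
gillespie_next_event <- function(propensities) {
  if (any(propensities < 0) || any(!is.finite(propensities)))
    stop("propensities must be finite and non-negative", call. = FALSE)
  total <- sum(propensities)
  if (total <= 0) return(list(dt = Inf, channel = NA_integer_))
  dt <- stats::rexp(1, total)
  channel <- sample.int(length(propensities), 1, prob = propensities)
  list(dt = dt, channel = channel)
}
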