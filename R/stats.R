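# Supporting statistics: two-sample chi-squared comparison against count
# data, one-at-a-time parameter sensitivity, half-life regression.

#' Two-sample chi-squared comparison
#'
#' Homogeneity test between experimentally observed and simulated counts
#' over the same categories (e.g. apoptotic / non-apoptotic).  The null
#' hypothesis is that experiment and simulation draw from the same category
#' distribution; the verdict uses `alpha`.
#'
#' @param observed named non-negative integer counts (experiment).
#' @param simulated counts over the same categories (simulation).
#' @param alpha significance level.
#' @return list with `statistic`, `df`, `p_value`, `same` (logical verdict),
#'   and `pooled` (categories dropped because both samples were empty).
#' @export
chi2_compare <- function(observed, simulated, alpha = 0.05) {
  if (length(observed) != length(simulated))
    stop("category mismatch", call. = FALSE)
  if (!is.null(names(observed)) && !is.null(names(simulated)) &&
      !identical(names(observed), names(simulated)))
    stop("category labels differ", call. = FALSE)
  if (any(observed < 0) || any(simulated < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (sum(observed) + sum(simulated) == 0)
    stop("all-zero table", call. = FALSE)
  empty <- observed + simulated == 0
  labels <- if (is.null(names(observed))) as.character(seq_along(observed))
    else names(observed)
  pooled <- labels[empty]
  observed <- observed[!empty]; simulated <- simulated[!empty]
  tab <- rbind(observed, simulated)
  if (ncol(tab) < 2 || identical(unname(observed), unname(simulated))) {
    # degenerate or identical samples: statistic 0 by definition
    if (identical(unname(observed), unname(simulated)))
      return(list(statistic = 0, df = ncol(tab) - 1, p_value = 1,
                  same = TRUE, pooled = pooled))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), same = ct$p.value > alpha,
       pooled = pooled)
}

#' Half-life from a decay time course
#'
#' Log-linear least squares of `ln(level)` on time (the standard exponential
#' approximation used on cycloheximide / actinomycin D chase series).
#'
#' @param times hours since the chase started (>= 3 points).
#' @param levels positive levels (arbitrary units; the estimate is
#'   scale-invariant).
#' @return list with `k` (decay rate, 1/s), `t_half_h` (hours; `Inf` when no
#'   decay is detectable), `r_squared`, and `decaying` (logical).
#' @export
fit_half_life <- function(times, levels) {
  if (length(times) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  if (!any(diff(levels) < 0))
    warning("series is non-decreasing; fit unconstrained")
  fit <- stats::lm(log(levels) ~ times)
  slope_h <- unname(stats::coef(fit)[2])       # 1/h
  k <- -slope_h / 3600
  r2 <- summary(fit)$r.squared
  t_half_h <- if (k > 0) log(2) / (k * 3600) else Inf
  list(k = k, t_half_h = t_half_h, r_squared = r2, decaying = k > 0)
}

#' One-at-a-time parameter sensitivity of fate outputs
#'
#' Perturbs each parameter by `+/- perturbation` (relative) and reruns the
#' population with identical per-cell seeds (common random numbers), so the
#' only difference between runs is the parameter value.  Relative
#' sensitivity is `S = (dY/Y) / (dp/p)` for the apoptotic fraction in the
#' last window and for viability.  A perturbation whose effect is smaller
#' than the Monte-Carlo error is flagged inconclusive rather than reported
#' as a true zero.
#'
#' @param spec a `ddr_model`.
#' @param protocol a `ddr_protocol`.
#' @param params parameter names; default: all parameters flagged fitted.
#' @param perturbation relative change (> 0), default 0.2.
#' @param n cells per run.
#' @param master_seed integer.
#' @param thresholds a [fate_thresholds()].
#' @param windows apoptosis windows (h).
#' @param ... passed to [run_population()].
#' @return data frame (parameter, S_apo_plus, S_apo_minus, S_surv_plus,
#'   S_surv_minus, apo_base, surv_base, mc_error_apo, mc_error_surv,
#'   inconclusive).
#' @export
sensitivity_analysis <- function(spec, protocol, params = NULL,
                                 perturbation = 0.2, n = 200,
                                 master_seed = 1, thresholds,
                                 windows = list(c(0, 24), c(24, 48)), ...) {
  stopifnot(perturbation > 0)
  if (is.null(params)) params <- spec$params$name[spec$params$fitted]
  outputs <- function(sp) {
    pop <- run_population(sp, protocol, n, master_seed = master_seed,
                          thresholds = thresholds, track = "P21", ...)
    fr <- apoptotic_fraction(pop$fates, windows, t0 = protocol$ir_start)
    c(apo = fr[length(fr)], surv = clonogenic_survival(pop$fates))
  }
  base <- outputs(spec)
  se <- sqrt(pmax(base * (1 - base), 0.25 / n) / n)
  rows <- lapply(params, function(pn) {
    v0 <- param_value(spec, pn)
    yp <- outputs(do.call(set_params, setNames(list(spec,
      v0 * (1 + perturbation)), c("spec", pn))))
    ym <- outputs(do.call(set_params, setNames(list(spec,
      v0 * (1 - perturbation)), c("spec", pn))))
    rel <- function(y, b) if (b > 0) (y - b) / b else 0
    data.frame(parameter = pn,
               S_apo_plus = rel(yp["apo"], base["apo"]) / perturbation,
               S_apo_minus = rel(ym["apo"], base["apo"]) / (-perturbation),
               S_surv_plus = rel(yp["surv"], base["surv"]) / perturbation,
               S_surv_minus = rel(ym["surv"], base["surv"]) /
                 (-perturbation),
               apo_base = base["apo"], surv_base = base["surv"],
               delta_apo_max = max(abs(yp["apo"] - base["apo"]),
                                   abs(ym["apo"] - base["apo"])),
               delta_surv_max = max(abs(yp["surv"] - base["surv"]),
                                    abs(ym["surv"] - base["surv"])),
               mc_error_apo = se["apo"], mc_error_surv = se["surv"],
               inconclusive =
                 max(abs(yp["apo"] - base["apo"]),
                     abs(ym["apo"] - base["apo"])) < 2 * se["apo"] &&
                 max(abs(yp["surv"] - base["surv"]),
                     abs(ym["surv"] - base["surv"])) < 2 * se["surv"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
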