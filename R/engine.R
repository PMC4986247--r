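# Hybrid engine wrapper: compiles the declarative model tables to flat
# arrays, drives the C++ RK4/Gillespie core, and returns trajectories.

#' Engine configuration
#'
#' @param dt deterministic step (s).
#' @param save_every sampling cadence (s); must be a multiple of `dt`.
#' @param t_end simulation horizon (s), counted from the treatment-reference
#'   time 0 (burn-in runs at negative times).
#' @param seed integer seed; every stochastic draw of the cell flows from it.
#' @param clip_negative clip transient negative levels to 0 (counted).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(dt = 0.1, save_every = 10, t_end = 951000,
                          seed = 1L, clip_negative = TRUE) {
  stopifnot(dt > 0, save_every >= dt, t_end > 0)
  if (abs(save_every / dt - round(save_every / dt)) > 1e-9)
    stop("save_every must be a multiple of dt", call. = FALSE)
  structure(list(dt = dt, save_every = save_every, t_end = t_end,
                 seed = as.integer(seed), clip_negative = clip_negative),
            class = "engine_config")
}

#' Compile a model for the C++ engine
#'
#' Flattens the reaction, gene and channel tables into index/constant arrays.
#' The compiled form evaluates the identical term table as the R reference
#' evaluator [rhs()].
#'
#' @param spec a `ddr_model`.
#' @return opaque list consumed by the engine.
#' @export
compile_model <- function(spec) {
  det <- spec$species[spec$species$partition == "deterministic", ]
  sidx <- function(nm) match(nm, det$name) - 1L
  ftype_code <- c(one = 0L, lin = 1L, mm = 2L, inh = 3L, hill = 4L,
                  gene = 5L, dsb = 6L, dsbmm = 7L, recept = 8L)
  gidx <- function(nm) match(nm, spec$genes$name) - 1L
  nT <- nrow(spec$reactions)
  t_ftype <- integer(3 * nT); t_fref <- integer(3 * nT)
  t_fK <- numeric(3 * nT); t_fn <- numeric(3 * nT)
  for (i in seq_len(nT)) {
    r <- spec$reactions[i, ]
    fs <- c(r$f1, r$f2, r$f3)
    for (k in 1:3) {
      f <- parse_factor(fs[k])
      j <- 3 * (i - 1) + k
      t_ftype[j] <- ftype_code[[f$type]]
      t_fref[j] <- if (f$type %in% c("lin", "mm", "inh", "hill"))
        sidx(f$ref) else if (f$type == "gene") gidx(f$ref) else 0L
      t_fK[j] <- if (!is.na(f$K)) param_value(spec, f$K) else 0
      t_fn[j] <- if (!is.na(f$n)) param_value(spec, f$n) else 1
    }
  }
  regs <- spec$gene_regs
  list(
    n_det = nrow(det),
    species_names = det$name,
    init = stats::setNames(det$init, det$name),
    gene_names = spec$genes$name,
    t_rate = vapply(spec$reactions$rate, function(p) param_value(spec, p),
                    numeric(1), USE.NAMES = FALSE),
    t_src = ifelse(is.na(spec$reactions$src), -1L,
                   sidx(spec$reactions$src)),
    t_dst = ifelse(is.na(spec$reactions$dst), -1L,
                   sidx(spec$reactions$dst)),
    t_ftype = t_ftype, t_fref = t_fref, t_fK = t_fK, t_fn = t_fn,
    g_q0 = vapply(spec$genes$q0, function(p) param_value(spec, p),
                  numeric(1), USE.NAMES = FALSE),
    g_deact = vapply(spec$genes$deact, function(p) param_value(spec, p),
                     numeric(1), USE.NAMES = FALSE),
    r_gene = if (nrow(regs)) gidx(regs$gene) else integer(0),
    r_species = if (nrow(regs)) sidx(regs$species) else integer(0),
    r_inh_species = if (nrow(regs))
      ifelse(is.na(regs$inh_species), -1L, sidx(regs$inh_species)) else
        integer(0),
    r_weight = if (nrow(regs))
      vapply(regs$weight, function(p) param_value(spec, p), numeric(1),
             USE.NAMES = FALSE) else numeric(0),
    r_inh_K = if (nrow(regs))
      vapply(seq_len(nrow(regs)), function(i)
        if (is.na(regs$inh_K[i])) 0 else param_value(spec, regs$inh_K[i]),
        numeric(1)) else numeric(0),
    dsb_k_per_gy = param_value(spec, spec$dsb$k_per_gy),
    dsb_background = param_value(spec, spec$dsb$background),
    dsb_vmax = param_value(spec, spec$dsb$vmax),
    dsb_km = param_value(spec, spec$dsb$km),
    rec_total = as.integer(param_value(spec, spec$receptors$total)),
    rec_k_act = param_value(spec, spec$receptors$k_act),
    rec_k_deact = param_value(spec, spec$receptors$k_deact))
}

#' Simulate one cell
#'
#' Advances a single cell through burn-in and treatment with the hybrid
#' scheme: fixed-step RK4 for the continuous species, direct Gillespie for
#' gene switching, DSB and receptor events.  Identical
#' (spec, protocol, cfg, seed) inputs give bit-identical trajectories.
#'
#' @param spec a `ddr_model` (or a pre-compiled model from
#'   [compile_model()]).
#' @param protocol a `ddr_protocol` from [make_protocol()].
#' @param cfg an [engine_config()]; `cfg$t_end` overrides the protocol
#'   horizon when smaller.
#' @param init optional named initial level vector (defaults to the model's
#'   declared resting levels).
#' @param genes0,dsb0,rec0 initial discrete state.
#' @param stochastic set `FALSE` to disable every event channel (pure ODE
#'   limit; discrete state stays frozen).
#' @return object of class `cell_trajectory`: a list with `times` (s), `Y`
#'   (time x species matrix), `G` (allele counts), `dsb`, `receptors`,
#'   `clip_count`.
#' @export
simulate_cell <- function(spec, protocol, cfg = engine_config(),
                          init = NULL, genes0 = NULL, dsb0 = 0L, rec0 = 0L,
                          stochastic = TRUE) {
  cm <- if (inherits(spec, "ddr_model")) compile_model(spec) else spec
  if (is.null(init)) init <- cm$init
  init <- init[cm$species_names]
  if (anyNA(init)) stop("init vector incomplete", call. = FALSE)
  if (is.null(genes0)) genes0 <- rep(2L, length(cm$gene_names))
  pl <- list(ir_start = protocol$ir_start,
             ir_stop = protocol$ir_start + protocol$ir_window,
             ir_rate_gy_s = protocol$ir_dose_rate / 60,
             tnf_start = protocol$tnf_start,
             tnf_stop = protocol$tnf_start + protocol$tnf_duration,
             tnf_level = protocol$tnf_dose)
  cl <- list(dt = cfg$dt, save_every = cfg$save_every,
             t_start = -protocol$burn_in,
             t_end = min(cfg$t_end, protocol$horizon),
             clip_negative = cfg$clip_negative, stochastic = stochastic)
  set.seed(cfg$seed)
  out <- simulate_cell_cpp(cm, as.numeric(init), as.integer(genes0),
                           as.integer(dsb0), as.integer(rec0), pl, cl)
  colnames(out$Y) <- cm$species_names
  colnames(out$G) <- cm$gene_names
  structure(out, class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("<cell_trajectory> ", length(x$times), " samples, t in [",
      x$times[1], ", ", x$times[length(x$times)], "] s\n", sep = "")
  invisible(x)
}

#' Locate the deterministic resting point
#'
#' Relaxes the mean-field system (gene states and DSB count treated as
#' continuous averages) with no irradiation and no TNF until the derivative
#' norm is below tolerance, starting from the model's declared levels.  This
#' is the burn-in fixed point used as the pre-treatment state.
#'
#' @param spec a `ddr_model`.
#' @param t_relax relaxation horizon (s).
#' @param dt relaxation step (s).
#' @param background include the spontaneous DSB background in the mean
#'   field (default `FALSE`: the strict no-damage fixed point).
#' @param genes fixed allele states: when supplied, gene states are held at
#'   these values and only the continuous species relax (the conditional
#'   resting point of a cell with that allele configuration).
#' @return list with `y` (named levels), `genes` (mean allele states),
#'   `dsb`, and `max_abs_deriv`.
#' @export
find_rest <- function(spec, t_relax = 6e5, dt = 5, background = FALSE,
                      genes = NULL) {
  cm <- compile_model(spec)
  if (!background) cm$dsb_background <- 0
  freeze <- !is.null(genes)
  g0 <- if (freeze) as.numeric(genes) else rep(1, length(cm$gene_names))
  res <- relax_meanfield_cpp(cm, as.numeric(cm$init), g0,
                             0, 0, 0, 0, dt, t_relax, freeze)
  dy <- rhs_cpp(cm, res$y, res$genes, res$dsb, 0)
  list(y = stats::setNames(res$y, cm$species_names),
       genes = stats::setNames(res$genes, cm$gene_names),
       dsb = res$dsb, max_abs_deriv = max(abs(dy)))
}
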