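#' @useDynLib ddrsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif setNames quantile chisq.test lm coef pchisq
NULL

COMPARTMENTS <- c("extracellular", "cytoplasm", "nucleus")
SPECIES_FORMS <- c("protein", "protein_phospho", "protein_multiphospho",
                   "mRNA", "miRNA", "complex")
FACTOR_TYPES <- c("one", "lin", "mm", "inh", "hill", "gene", "dsb", "dsbmm",
                  "recept")

#' Declare one molecular species
#'
#' A species lives in exactly one of the three well-mixed compartments
#' (extracellular space, cytoplasm, nucleus) and belongs to exactly one
#' simulation partition.  Continuous (deterministic) species are advanced by
#' the ODE integrator; stochastic species are integer counters advanced by
#' discrete events.
#'
#' @param name identifier, used in reaction terms.
#' @param compartment one of `"extracellular"`, `"cytoplasm"`, `"nucleus"`.
#' @param form molecular form, e.g. `"protein"`, `"mRNA"`.
#' @param partition `"deterministic"` or `"stochastic"`.
#' @param init resting-level initial value (molecules per cell).
#' @return one-row data frame.
#' @export
ddr_species <- function(name, compartment, form, partition = "deterministic",
                        init = 0) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  form <- match.arg(form, SPECIES_FORMS)
  partition <- match.arg(partition, c("deterministic", "stochastic"))
  data.frame(name = name, compartment = compartment, form = form,
             partition = partition, init = init, stringsAsFactors = FALSE)
}

#' Declare one reaction term
#'
#' Each term contributes a single flux `k * f1 * f2 * f3` (molecules/s) where
#' `k` is a named rate parameter and each factor is one of:
#' \describe{
#'   \item{`"lin:X"`}{level of species X}
#'   \item{`"mm:X:K"`}{Michaelis-Menten saturation `X/(K+X)` (enzymatic
#'     (de)phosphorylation substrates)}
#'   \item{`"inh:X:K"`}{inhibition `K/(K+X)`}
#'   \item{`"hill:X:K:n"`}{Hill saturation `X^n/(K^n+X^n)`}
#'   \item{`"gene:g"`}{active allele count of gene g (0, 1 or 2)}
#'   \item{`"dsb"`}{current unrepaired double-strand-break count}
#'   \item{`"dsbmm:K"`}{`dsb/(K+dsb)`}
#'   \item{`"recept"`}{active TNF receptor count}
#' }
#' `K` and `n` are names of entries in the parameter table so that every
#' numeric constant lives in one reviewable place.  The flux is removed from
#' `src` and added to `dst`; either may be `NA` (pure synthesis or pure
#' degradation).  Terms with `transport = TRUE` additionally assert at load
#' time that `src` and `dst` are the same molecule in different compartments.
#'
#' @param name unique term identifier.
#' @param rate name of the rate parameter.
#' @param src species losing the flux, or `NA`.
#' @param dst species gaining the flux, or `NA`.
#' @param f1,f2,f3 factor strings as above, or `NULL`.
#' @param transport logical; marks cross-compartment shuttling terms.
#' @return one-row data frame.
#' @export
ddr_reaction <- function(name, rate, src = NA_character_, dst = NA_character_,
                         f1 = NULL, f2 = NULL, f3 = NULL, transport = FALSE) {
  data.frame(name = name, rate = rate, src = src, dst = dst,
             f1 = if (is.null(f1)) NA_character_ else f1,
             f2 = if (is.null(f2)) NA_character_ else f2,
             f3 = if (is.null(f3)) NA_character_ else f3,
             transport = transport, stringsAsFactors = FALSE)
}

parse_factor <- function(s) {
  if (is.na(s)) return(list(type = "one", ref = NA, K = NA, n = NA))
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  type <- parts[1]
  if (!type %in% FACTOR_TYPES)
    stop("unknown factor type '", type, "'", call. = FALSE)
  switch(type,
    one    = list(type = type, ref = NA, K = NA, n = NA),
    lin    = list(type = type, ref = parts[2], K = NA, n = NA),
    mm     = list(type = type, ref = parts[2], K = parts[3], n = NA),
    inh    = list(type = type, ref = parts[2], K = parts[3], n = NA),
    hill   = list(type = type, ref = parts[2], K = parts[3], n = parts[4]),
    gene   = list(type = type, ref = parts[2], K = NA, n = NA),
    dsb    = list(type = type, ref = NA, K = NA, n = NA),
    dsbmm  = list(type = type, ref = NA, K = parts[2], n = NA),
    recept = list(type = type, ref = NA, K = NA, n = NA))
}

#' Assemble and validate a full model specification
#'
#' Bundles the declarative tables (species, parameters, reaction terms, gene
#' definitions and regulator table, DSB channel, TNF receptor channel) into a
#' validated `ddr_model` object.  Validation resolves every symbol used in a
#' reaction factor or gene regulator: an unknown species, gene or parameter
#' name is a load-time error naming the offending symbol.
#'
#' @param species data frame of [ddr_species()] rows.
#' @param params data frame with columns `name`, `value` and optionally
#'   `fitted` (logical), `half_life` (seconds; for degradation parameters the
#'   value must equal `log(2)/half_life`) and `desc`.
#' @param reactions data frame of [ddr_reaction()] rows.
#' @param genes data frame with columns `name`, `q0`, `deact` (the latter two
#'   are parameter names: basal activation propensity and per-allele
#'   deactivation rate).
#' @param gene_regs data frame with columns `gene`, `species`, `weight`
#'   (parameter name) and optional `inh_species`, `inh_K` describing an
#'   activator contribution `weight * level`, optionally multiplied by
#'   `inh_K/(inh_K + inh_level)`.
#' @param dsb list with parameter names `k_per_gy`, `background`, `vmax`,
#'   `km` for the damage induction/repair channel.
#' @param receptors list with parameter names `total`, `k_act`, `k_deact`.
#' @param name model name.
#' @return object of class `ddr_model`.
#' @export
ddr_model <- function(species, params, reactions, genes, gene_regs,
                      dsb, receptors, name = "ddr") {
  if (!"fitted" %in% names(params)) params$fitted <- FALSE
  if (!"half_life" %in% names(params)) params$half_life <- NA_real_
  if (anyDuplicated(species$name))
    stop("duplicate species name", call. = FALSE)
  if (anyDuplicated(params$name))
    stop("duplicate parameter name", call. = FALSE)
  spec <- structure(list(name = name, species = species, params = params,
                         reactions = reactions, genes = genes,
                         gene_regs = gene_regs, dsb = dsb,
                         receptors = receptors),
                    class = "ddr_model")
  validate_model(spec)
  spec
}

param_value <- function(spec, pname) {
  i <- match(pname, spec$params$name)
  if (is.na(i)) stop("unresolved parameter '", pname, "'", call. = FALSE)
  spec$params$value[i]
}

#' Validate a model specification
#'
#' @param spec a `ddr_model`.
#' @return the spec, invisibly; errors name the first unresolved symbol.
#' @export
validate_model <- function(spec) {
  sp <- spec$species
  stopifnot(all(sp$compartment %in% COMPARTMENTS))
  det <- sp$name[sp$partition == "deterministic"]
  if (any(spec$params$value < 0))
    stop("negative rate parameter: ",
         spec$params$name[which(spec$params$value < 0)[1]], call. = FALSE)
  hl <- spec$params
  hl <- hl[!is.na(hl$half_life), ]
  if (nrow(hl) > 0) {
    bad <- abs(hl$value - log(2) / hl$half_life) >
      1e-9 * pmax(hl$value, 1e-300)
    if (any(bad))
      stop("degradation rate inconsistent with declared half-life: ",
           hl$name[which(bad)[1]], call. = FALSE)
  }
  for (i in seq_len(nrow(spec$reactions))) {
    r <- spec$reactions[i, ]
    param_value(spec, r$rate)
    for (sym in c(r$src, r$dst))
      if (!is.na(sym) && !sym %in% det)
        stop("unresolved species '", sym, "' in term '", r$name, "'",
             call. = FALSE)
    if (isTRUE(r$transport)) {
      if (is.na(r$src) || is.na(r$dst))
        stop("transport term '", r$name, "' must name both compartments",
             call. = FALSE)
      cs <- sp$compartment[match(c(r$src, r$dst), sp$name)]
      if (cs[1] == cs[2])
        stop("transport term '", r$name, "' does not cross compartments",
             call. = FALSE)
    }
    for (fs in c(r$f1, r$f2, r$f3)) {
      f <- parse_factor(fs)
      if (f$type %in% c("lin", "mm", "inh", "hill") && !f$ref %in% det)
        stop("unresolved species '", f$ref, "' in term '", r$name, "'",
             call. = FALSE)
      if (f$type == "gene" && !f$ref %in% spec$genes$name)
        stop("unresolved gene '", f$ref, "' in term '", r$name, "'",
             call. = FALSE)
      if (!is.na(f$K)) param_value(spec, f$K)
      if (!is.na(f$n)) param_value(spec, f$n)
    }
  }
  for (g in seq_len(nrow(spec$genes))) {
    param_value(spec, spec$genes$q0[g])
    param_value(spec, spec$genes$deact[g])
  }
  if (nrow(spec$gene_regs) > 0) {
    for (i in seq_len(nrow(spec$gene_regs))) {
      gr <- spec$gene_regs[i, ]
      if (!gr$gene %in% spec$genes$name)
        stop("unresolved gene '", gr$gene, "' in gene_regs", call. = FALSE)
      if (!gr$species %in% det)
        stop("unresolved species '", gr$species, "' in gene_regs",
             call. = FALSE)
      param_value(spec, gr$weight)
      if (!is.na(gr$inh_species)) {
        if (!gr$inh_species %in% det)
          stop("unresolved species '", gr$inh_species, "' in gene_regs",
               call. = FALSE)
        param_value(spec, gr$inh_K)
      }
    }
  }
  for (pn in unlist(spec$dsb)) param_value(spec, pn)
  for (pn in unlist(spec$receptors)) param_value(spec, pn)
  invisible(spec)
}

#' Construct the dynamic state of one cell
#'
#' @param spec a `ddr_model`.
#' @param t time (seconds).
#' @param y named vector of continuous species levels; defaults to the
#'   spec's declared initial levels.
#' @param genes named integer vector of active allele counts in `{0,1,2}`.
#' @param dsb unrepaired double-strand-break count.
#' @param receptors_active active TNF receptor count.
#' @return list of class `cell_state`.
#' @export
cell_state <- function(spec, t = 0, y = NULL, genes = NULL, dsb = 0,
                       receptors_active = 0) {
  det <- spec$species[spec$species$partition == "deterministic", ]
  if (is.null(y)) y <- setNames(det$init, det$name)
  y <- y[det$name]
  if (anyNA(y)) stop("state vector missing species", call. = FALSE)
  if (is.null(genes)) genes <- setNames(rep(2L, nrow(spec$genes)),
                                        spec$genes$name)
  if (!all(genes %in% 0:2)) stop("gene allele counts must be in {0,1,2}",
                                 call. = FALSE)
  structure(list(t = t, y = y, genes = genes, dsb = dsb,
                 receptors_active = receptors_active),
            class = "cell_state")
}

eval_factor <- function(f, state, spec) {
  switch(f$type,
    one    = 1,
    lin    = unname(state$y[f$ref]),
    mm     = { K <- param_value(spec, f$K); x <- unname(state$y[f$ref])
               x / (K + x) },
    inh    = { K <- param_value(spec, f$K); x <- unname(state$y[f$ref])
               K / (K + x) },
    hill   = { K <- param_value(spec, f$K); n <- param_value(spec, f$n)
               x <- unname(state$y[f$ref]); x^n / (K^n + x^n) },
    gene   = unname(state$genes[f$ref]),
    dsb    = state$dsb,
    dsbmm  = { K <- param_value(spec, f$K); state$dsb / (K + state$dsb) },
    recept = state$receptors_active)
}

term_flux <- function(r, state, spec) {
  v <- param_value(spec, r$rate)
  for (fs in c(r$f1, r$f2, r$f3)) {
    f <- parse_factor(fs)
    if (f$type != "one") v <- v * eval_factor(f, state, spec)
  }
  v
}

#' Deterministic right-hand side
#'
#' Evaluates dy/dt (molecules per second) for the continuous partition at a
#' frozen discrete state (gene allele counts, DSB count, receptor count).
#' This is the reference evaluator; the compiled engine evaluates the same
#' reaction table.
#'
#' @param state a `cell_state` with finite, non-negative levels.
#' @param spec a `ddr_model`.
#' @return named derivative vector over the deterministic species.
#' @export
rhs <- function(state, spec) {
  if (any(!is.finite(state$y)) || any(state$y < 0))
    stop("species levels must be finite and non-negative", call. = FALSE)
  dy <- setNames(numeric(length(state$y)), names(state$y))
  for (i in seq_len(nrow(spec$reactions))) {
    r <- spec$reactions[i, ]
    v <- term_flux(r, state, spec)
    if (!is.na(r$src)) dy[r$src] <- dy[r$src] - v
    if (!is.na(r$dst)) dy[r$dst] <- dy[r$dst] + v
  }
  dy
}

#' Cross-compartment transport contributions
#'
#' Returns the contribution of the shuttling terms only.  Every transport
#' flux appears twice with opposite signs, so summing a shuttled molecule
#' over its compartments cancels transport exactly.
#'
#' @inheritParams rhs
#' @return named vector over the deterministic species (zero for species not
#'   involved in transport).
#' @export
transport_terms <- function(state, spec) {
  dy <- setNames(numeric(length(state$y)), names(state$y))
  tr <- spec$reactions[spec$reactions$transport, ]
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    v <- term_flux(r, state, spec)
    dy[r$src] <- dy[r$src] - v
    dy[r$dst] <- dy[r$dst] + v
  }
  dy
}

#' Serialize a model to YAML
#'
#' The species, parameter, reaction and gene tables round-trip losslessly.
#'
#' @param spec a `ddr_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
model_to_yaml <- function(spec, path) {
  obj <- list(name = spec$name,
              species = spec$species, params = spec$params,
              reactions = spec$reactions, genes = spec$genes,
              gene_regs = spec$gene_regs, dsb = spec$dsb,
              receptors = spec$receptors)
  yaml::write_yaml(obj, path, column.major = FALSE, precision = 15)
  invisible(path)
}

#' Load a model from YAML
#'
#' @param path file written by [model_to_yaml()].
#' @return a validated `ddr_model`.
#' @export
model_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  as_df <- function(x) {
    do.call(rbind, lapply(x, function(row)
      as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  }
  ddr_model(species = as_df(obj$species), params = as_df(obj$params),
            reactions = as_df(obj$reactions), genes = as_df(obj$genes),
            gene_regs = if (length(obj$gene_regs)) as_df(obj$gene_regs) else
              data.frame(gene = character(), species = character(),
                         weight = character(), inh_species = character(),
                         inh_K = character(), stringsAsFactors = FALSE),
            dsb = obj$dsb, receptors = obj$receptors, name = obj$name)
}

#' @export
print.ddr_model <- function(x, ...) {
  det <- sum(x$species$partition == "deterministic")
  cat("<ddr_model> ", x$name, "\n", sep = "")
  cat("  continuous species: ", det, " in ",
      length(unique(x$species$compartment)), " compartments\n", sep = "")
  cat("  reaction terms:     ", nrow(x$reactions), "\n", sep = "")
  cat("  stochastic genes:   ", paste(x$genes$name, collapse = ", "), "\n",
      sep = "")
  cat("  parameters:         ", nrow(x$params), "\n", sep = "")
  invisible(x)
}
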