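#' Solve a phase- and knockout-constrained flux balance problem
#'
#' Maximises the biomass objective subject to steady-state mass balance
#' \eqn{S v = 0} and flux bounds, after (i) disabling reactions whose boolean
#' gene-association evaluates false with the knocked-out gene set false and
#' (ii) applying phase-matched regulatory rules. Among alternate optima the
#' minimum-norm flux vector is returned (a parsimonious secondary objective,
#' implemented as a tiny ridge on the LP) so downstream statistics see
#' deterministic fluxes.
#'
#' @param model a `stoich_model`.
#' @param rules optional `regulatory_rules`.
#' @param knockout gene id to delete, or `NULL` for wild type.
#' @param phase `"pre"` (glucose/fermentative) or `"post"` (ethanol/respiratory).
#' @param bounds optional list(lb, ub) overriding the model bounds (used by
#'   the dynamic FBA driver); regulatory constraints are applied on top.
#' @return a `flux_solution`: list with `v` (named flux vector), `objective`
#'   (1/h) and `status` (`"optimal"` or `"infeasible"`; infeasible problems
#'   report objective 0 by convention).
#' @export
solve_fba <- function(model, rules = NULL, knockout = NULL,
                      phase = c("pre", "post"), bounds = NULL) {
  phase <- match.arg(phase)
  if (!is.null(knockout) && !knockout %in% c(model$genes, rule_genes(rules %||% data.frame(gene = character())))) {
    stop("knockout gene not in the model or rule set: ", knockout)
  }
  base <- model
  if (!is.null(bounds)) {
    base$lb <- bounds$lb
    base$ub <- bounds$ub
  }
  bb <- constrained_bounds(base, rules, knockout, phase)
  obj <- as.numeric(model$reactions == model$objective)
  sol <- lp_bounded(obj, model$S, rep(0, nrow(model$S)), bb$lb, bb$ub)
  if (sol$status != "optimal") {
    return(structure(list(
      v = stats::setNames(rep(NA_real_, ncol(model$S)), model$reactions),
      objective = 0, status = "infeasible"), class = "flux_solution"))
  }
  structure(list(v = stats::setNames(sol$x, model$reactions),
                 objective = max(sol$objective, 0),
                 status = "optimal"), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %.6g\n",
              x$status, x$objective))
  invisible(x)
}

#' Dynamic FBA across the diauxic shift (static optimisation approach)
#'
#' Forward-Euler loop: at each step the glucose and ethanol uptake bounds are
#' set by Michaelis-Menten functions of the current extracellular pools, an
#' FBA problem is solved, and biomass and pools are updated. The regulatory
#' phase flips from `pre` to `post` when glucose falls below a fraction of
#' its initial concentration (glucose exhaustion / derepression).
#'
#' @inheritParams solve_fba
#' @param glucose0 initial glucose (mmol/L); must be positive.
#' @param biomass0 initial biomass (gDW/L).
#' @param ethanol0 initial ethanol (mmol/L).
#' @param dt Euler step (h).
#' @param horizon simulated time (h).
#' @param depletion_frac glucose fraction of `glucose0` below which the
#'   regulatory phase flips to `post`.
#' @return a `dfba_trajectory`: data.frame columns `time`, `biomass`,
#'   `glucose`, `ethanol`, `growth_rate`, `phase`, plus attributes
#'   `shift_time`, `pre_rate`, `post_rate` (biomass-weighted mean growth rate
#'   per phase).
#' @export
run_dfba <- function(model, rules = NULL, knockout = NULL,
                     glucose0 = 20, biomass0 = 0.05, ethanol0 = 0,
                     dt = 0.1, horizon = 30, depletion_frac = 0.01) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(horizon, "horizon", positive = TRUE)
  stopifnot_scalar_number(glucose0, "glucose0", positive = TRUE)
  kin <- model$uptake_kinetics
  ex <- model$exchanges
  for (nm in c("glucose_uptake", "ethanol_uptake", "ethanol_secretion")) {
    if (is.null(ex[[nm]])) stop("model$exchanges must name ", nm)
  }
  vmax_g <- kin$vmax_glc %||% 0.4
  km_g <- kin$km_glc %||% 0.5
  vmax_e <- kin$vmax_eth %||% 0.3
  km_e <- kin$km_eth %||% 0.5
  nstep <- ceiling(horizon / dt)
  time <- seq(0, by = dt, length.out = nstep + 1)
  X <- G <- E <- mu <- numeric(nstep + 1)
  ph <- character(nstep + 1)
  X[1] <- biomass0; G[1] <- glucose0; E[1] <- ethanol0
  shift_time <- NA_real_
  for (k in seq_len(nstep)) {
    phase <- if (G[k] >= depletion_frac * glucose0) "pre" else "post"
    if (phase == "post" && is.na(shift_time)) shift_time <- time[k]
    lb <- model$lb; ub <- model$ub
    ub[ex$glucose_uptake] <- min(ub[ex$glucose_uptake],
                                 vmax_g * G[k] / (km_g + G[k]))
    ub[ex$ethanol_uptake] <- min(ub[ex$ethanol_uptake],
                                 vmax_e * E[k] / (km_e + E[k]))
    sol <- solve_fba(model, rules, knockout, phase,
                     bounds = list(lb = lb, ub = ub))
    ph[k] <- phase
    if (sol$status != "optimal") {
      mu[k] <- 0
      X[k + 1] <- X[k]; G[k + 1] <- G[k]; E[k + 1] <- E[k]
      next
    }
    mu[k] <- sol$objective
    v_g <- sol$v[ex$glucose_uptake]
    v_eu <- sol$v[ex$ethanol_uptake]
    v_es <- sol$v[ex$ethanol_secretion]
    X[k + 1] <- X[k] * exp(mu[k] * dt)
    G[k + 1] <- max(0, G[k] - v_g * X[k] * dt)
    E[k + 1] <- max(0, E[k] + (v_es - v_eu) * X[k] * dt)
    # static state: nothing will change any more, so extend and stop early
    if (mu[k] == 0 && v_g * X[k] * dt < 1e-12 && abs(v_es - v_eu) * X[k] * dt < 1e-12) {
      idx <- (k + 1):(nstep + 1)
      X[idx] <- X[k]; G[idx] <- G[k]; E[idx] <- E[k]
      mu[idx[-length(idx)]] <- 0
      ph[idx] <- phase
      if (phase == "pre" && any(G[idx] < depletion_frac * glucose0)) ph[idx] <- "post"
      break
    }
  }
  ph[nstep + 1] <- if (G[nstep + 1] >= depletion_frac * glucose0) "pre" else "post"
  if (nzchar(ph[nstep + 1]) && ph[nstep + 1] == "post" && is.na(shift_time)) {
    shift_time <- time[nstep + 1]
  }
  ph[!nzchar(ph)] <- "post"
  traj <- data.frame(time = time, biomass = X, glucose = G, ethanol = E,
                     growth_rate = mu, phase = ph)
  steps <- seq_len(nstep)
  wmean <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(mu[steps][sel] * X[steps][sel]) / sum(X[steps][sel])
  }
  pre_rate <- wmean(ph[steps] == "pre")
  post_rate <- wmean(ph[steps] == "post")
  structure(traj, class = c("dfba_trajectory", "data.frame"),
            shift_time = shift_time,
            pre_rate = if (is.na(pre_rate)) 0 else pre_rate,
            post_rate = post_rate)
}

#' Rank deletion strains by between-variant post-shift growth discrepancy
#'
#' For every gene in `genes`, simulates the deletion strain under both
#' regulatory rule sets with [run_dfba()] and reports the absolute difference
#' in post-shift growth rate. Strains that are non-viable under both variants
#' in both phases are excluded (only fully viable deletants are candidates
#' for follow-up). Ties break deterministically by gene id.
#'
#' @inheritParams run_dfba
#' @param rules_a,rules_b the two `regulatory_rules` variants to compare.
#' @param genes character vector of genes to knock out.
#' @param top_k optionally truncate the table to the top `top_k` rows.
#' @param ... passed to [run_dfba()].
#' @return data.frame with columns `gene`, `growth_a`, `growth_b`,
#'   `abs_diff`, sorted by decreasing `abs_diff`.
#' @export
rank_strains <- function(model, rules_a, rules_b, genes, top_k = NULL, ...) {
  if (length(genes) == 0) stop("empty gene list")
  rows <- lapply(genes, function(g) {
    ta <- run_dfba(model, rules_a, knockout = g, ...)
    tb <- run_dfba(model, rules_b, knockout = g, ...)
    pa <- attr(ta, "post_rate"); pa <- if (is.na(pa)) 0 else pa
    pb <- attr(tb, "post_rate"); pb <- if (is.na(pb)) 0 else pb
    viable <- (attr(ta, "pre_rate") > 0 || pa > 0) ||
      (attr(tb, "pre_rate") > 0 || pb > 0)
    data.frame(gene = g, growth_a = pa, growth_b = pb,
               abs_diff = abs(pb - pa), viable = viable)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$viable, setdiff(names(tab), "viable"), drop = FALSE]
  tab <- tab[order(-tab$abs_diff, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  tab
}

#' Replicate FBA solutions with jittered exchange bounds
#'
#' Produces the replicate "simulations" used as observations by the
#' model-validation statistics: each replicate re-solves the FBA problem with
#' every exchange-reaction bound multiplied by an independent
#' Uniform(1 - jitter, 1 + jitter) draw. Seeded and deterministic.
#'
#' @inheritParams solve_fba
#' @param n_replicates number of replicate solutions (>= 2; the study design
#'   uses 13).
#' @param jitter_fraction relative half-width of the bound jitter.
#' @param seed integer seed.
#' @return numeric matrix, reactions x replicates.
#' @export
replicate_fluxes <- function(model, rules = NULL, knockout = NULL,
                             phase = c("pre", "post"), n_replicates = 13,
                             jitter_fraction = 0.05, seed = 1) {
  phase <- match.arg(phase)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  ex_rxns <- unique(unlist(model$exchanges))
  if (is.null(ex_rxns) || !length(ex_rxns)) {
    # fall back: reactions touching a single metabolite act as exchanges
    ex_rxns <- model$reactions[colSums(model$S != 0) == 1]
  }
  out <- matrix(NA_real_, nrow = ncol(model$S), ncol = n_replicates,
                dimnames = list(model$reactions, paste0("rep", seq_len(n_replicates))))
  n_ok <- 0
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      lb <- model$lb; ub <- model$ub
      for (rx in ex_rxns) {
        f <- stats::runif(1, 1 - jitter_fraction, 1 + jitter_fraction)
        lb[rx] <- lb[rx] * f
        ub[rx] <- ub[rx] * f
      }
      sol <- solve_fba(model, rules, knockout, phase,
                       bounds = list(lb = lb, ub = ub))
      if (sol$status == "optimal") {
        out[, r] <- sol$v
        n_ok <- n_ok + 1
      } else {
        out[, r] <- 0  # lethal/blocked replicate: zero-flux convention
      }
    }
  })
  if (n_ok == 0) stop("all replicate FBA problems were infeasible")
  out
}
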