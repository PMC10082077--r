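#' Generate a toy metabolic model with two regulatory rule-set variants
#'
#' Builds a minimal yeast-like network that exhibits a diauxic shift under
#' dynamic FBA: a glucose uptake/glycolysis chain producing pyruvate, ATP and
#' NADH; a fermentative branch secreting ethanol (the only NADH sink before
#' the shift); a respiratory branch (NADH to ATP) and an ethanol-assimilation
#' branch, both repressed before the shift by unconditional `pre`-phase rules
#' (glucose repression); and an ATP- and pyruvate-consuming biomass drain.
#'
#' Two regulatory rule sets are returned. They share the constitutive
#' glucose-repression rules and a set of decoy regulator annotations; the
#' second variant (`M1Smart`) additionally records that one regulator gene is
#' required for ethanol assimilation after the shift. Deleting that gene
#' abolishes post-shift growth under the second variant only, which is the
#' planted ground truth the strain-ranking step must recover.
#'
#' @param n_internal_mets minimum number of internal metabolites (>= 4; the
#'   core network uses 5, larger values pad the glycolysis chain).
#' @param n_regulator_genes number of regulator genes annotated in the rule
#'   sets (>= 1; one is the planted affected gene, the rest are decoys with
#'   identical annotations in both variants).
#' @param seed integer seed; fixed seed gives field-for-field identical output.
#' @param max_retries regeneration attempts if a draw yields a model where
#'   the wild type cannot grow under both variants in both phases.
#' @return list with elements `model` (`stoich_model`), `rules_m1`,
#'   `rules_m1smart` (`regulatory_rules`) and `truth` (a `ground_truth` list
#'   with `affected_genes` and the decoy gene ids).
#' @export
make_toy_model_pair <- function(n_internal_mets = 5, n_regulator_genes = 4,
                                seed = 1, max_retries = 5) {
  if (n_internal_mets < 4) stop("n_internal_mets must be >= 4")
  if (n_regulator_genes < 1) stop("n_regulator_genes must be >= 1")
  for (attempt in seq_len(max_retries)) {
    out <- with_seed(seed + (attempt - 1L) * 100003L,
                     build_toy_pair(n_internal_mets, n_regulator_genes))
    ok <- all(vapply(c("pre", "post"), function(ph) {
      solve_fba(out$model, out$rules_m1, NULL, ph)$objective > 1e-9 &&
        solve_fba(out$model, out$rules_m1smart, NULL, ph)$objective > 1e-9
    }, logical(1)))
    if (ok) return(out)
  }
  stop("could not generate a toy model pair with a viable wild type after ",
       max_retries, " attempts (seed ", seed, ")")
}

build_toy_pair <- function(n_internal_mets, n_regulator_genes) {
  n_pad <- max(0L, n_internal_mets - 5L)
  pads <- if (n_pad) paste0("INT", seq_len(n_pad)) else character()
  mets <- c("GLC", pads, "PYR", "ETH", "ATP", "NADH")

  # randomized (but seed-deterministic) yields and kinetics
  y_resp <- stats::runif(1, 1.6, 2.4)     # ATP per NADH respired
  atp_bio <- stats::runif(1, 1.8, 2.6)    # ATP per biomass unit
  vmax_glc <- stats::runif(1, 0.3, 0.45)  # mmol/gDW/h
  vmax_eth <- stats::runif(1, 0.25, 0.4)

  rxn <- list()  # each: list(stoich = named numeric, lb, ub, gpr)
  add <- function(id, stoich, lb, ub, gpr) rxn[[id]] <<- list(s = stoich, lb = lb, ub = ub, gpr = gpr)
  add("GLC_upt", c(GLC = 1), 0, 10, "gHXT1")
  chain <- c("GLC", pads)
  for (i in seq_along(pads)) {
    add(paste0("GLY_", i), stats::setNames(c(-1, 1), c(chain[i], chain[i + 1])),
        0, 1000, paste0("gGLY", i + 1))
  }
  last <- chain[length(chain)]
  add("GLYC", stats::setNames(c(-1, 2, 2, 2), c(last, "PYR", "ATP", "NADH")),
      0, 1000, "gGLY1")
  add("FERM", c(PYR = -1, NADH = -1, ETH = 1), 0, 1000, "gPDC1")
  add("ETH_sec", c(ETH = -1), 0, 1000, "")
  add("ETH_upt", c(ETH = 1), 0, 10, "")
  add("ETHASS", c(ETH = -1, PYR = 2 / 3, NADH = 1), 0, 1000, "gADH2")
  add("RESP", stats::setNames(c(-1, y_resp), c("NADH", "ATP")), 0, 1000, "gRSP1")
  add("ATPM", c(ATP = -1), 0, 1000, "")
  add("BIOMASS", stats::setNames(c(-1, -atp_bio, -1), c("PYR", "ATP", "NADH")),
      0, 1000, "")

  S <- matrix(0, nrow = length(mets), ncol = length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in names(rxn)) S[names(rxn[[j]]$s), j] <- rxn[[j]]$s
  regulators <- paste0("RG", LETTERS[seq_len(n_regulator_genes)], "1")
  gprs <- vapply(rxn, `[[`, character(1), "gpr")
  model <- stoichiometric_model(
    S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    gpr = gprs,
    genes = c(unique(unlist(lapply(gprs, gpr_genes))), regulators),
    objective = "BIOMASS",
    exchanges = list(glucose_uptake = "GLC_upt", ethanol_uptake = "ETH_upt",
                     ethanol_secretion = "ETH_sec"),
    uptake_kinetics = list(vmax_glc = vmax_glc, km_glc = 0.5,
                           vmax_eth = vmax_eth, km_eth = 0.5)
  )

  affected <- sample(regulators, 1)
  decoys <- setdiff(regulators, affected)

  base <- data.frame(
    gene = c("-", "-", "-"),
    phase = c("pre", "pre", "post"),
    reaction = c("RESP", "ETHASS", "GLC_upt"),
    action = "disable",
    factor = 0.5,
    stringsAsFactors = FALSE
  )
  # decoy annotations: identical in both variants and growth-neutral
  # (they constrain reactions already silenced in the rule's phase)
  decoy_rules <- if (length(decoys)) {
    data.frame(gene = decoys,
               phase = "pre",
               reaction = sample(c("RESP", "ETHASS"), length(decoys), replace = TRUE),
               action = "disable", factor = 0.5, stringsAsFactors = FALSE)
  } else NULL
  m1 <- rbind(base, decoy_rules)
  m1smart <- rbind(m1, data.frame(gene = affected, phase = "post",
                                  reaction = "ETHASS", action = "disable",
                                  factor = 0.5, stringsAsFactors = FALSE))
  truth <- structure(list(affected_genes = affected,
                          decoy_genes = decoys,
                          regulator_genes = regulators),
                     class = "ground_truth")
  list(model = model,
       rules_m1 = regulatory_rules(m1, "M1", model),
       rules_m1smart = regulatory_rules(m1smart, "M1Smart", model),
       truth = truth)
}
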