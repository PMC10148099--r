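# Generators for toy metabolic models with analytically known screen
# outcomes. All internal reactions are unit-stoichiometry single-substrate,
# single-product conversions, so maximal fluxes follow min-cut arithmetic
# and small fixtures can be checked against independent oracles.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a linear-chain toy model
#'
#' Builds `EX_in -> M1 -> M2 -> ... -> EX_out` with one internal reaction
#' `Ri: Mi -> Mi+1` per entry of `ubs`. With a unique smallest upper bound
#' (the bottleneck) every internal reaction's FBA maximum equals that bound,
#' which makes knockdown arithmetic on the chain exact.
#'
#' @param ubs numeric upper bounds of the internal reactions, in order.
#' @param lbs lower bounds (default all 0, irreversible).
#' @param genes character vector of gene ids per internal reaction
#'   (`NA`/`""` for none).
#' @param subsystems subsystem label(s), recycled over internal reactions.
#' @param exchange_ub bound of the boundary exchanges (default 1000).
#' @param bottleneck_index if given, checked to carry the strictly smallest
#'   upper-bound magnitude among internal reactions.
#' @return A `metabolic_model`.
#' @export
#' @examples
#' m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "HIBCH", NA))
#' maximize_flux(m, "R1")$objective_value  # 10: chained through the bottleneck
make_linear_chain <- function(ubs, lbs = rep(0, length(ubs)), genes = NULL,
                              subsystems = "Pathway", exchange_ub = 1000,
                              bottleneck_index = NULL) {
  n <- length(ubs)
  stopifnot(n >= 1, length(lbs) == n)
  if (is.null(genes)) genes <- rep(NA_character_, n)
  stopifnot(length(genes) == n)
  subsystems <- rep_len(subsystems, n)
  if (!is.null(bottleneck_index)) {
    others <- abs(ubs[-bottleneck_index])
    if (length(others) && any(others <= abs(ubs[bottleneck_index]))) {
      stop("bottleneck_index does not carry the strictly smallest bound")
    }
  }
  met_ids <- paste0("M", seq_len(n + 1))
  mets <- data.frame(id = met_ids, name = met_ids, compartment = "c",
                     stringsAsFactors = FALSE)
  rxn_ids <- c("EX_in", paste0("R", seq_len(n)), "EX_out")
  rules <- c("", ifelse(is.na(genes) | genes == "", "", genes), "")
  rxns <- data.frame(
    id = rxn_ids, name = rxn_ids,
    lower_bound = c(0, lbs, 0),
    upper_bound = c(exchange_ub, ubs, exchange_ub),
    gene_rule = rules,
    subsystem = c("Exchange", subsystems, "Exchange"),
    stringsAsFactors = FALSE)
  sto <- c(
    list(EX_in = c(M1 = 1)),
    stats::setNames(lapply(seq_len(n), function(i) {
      stats::setNames(c(-1, 1), met_ids[c(i, i + 1)])
    }), paste0("R", seq_len(n))),
    stats::setNames(list(stats::setNames(-1, met_ids[n + 1])), "EX_out"))
  metabolic_model("linear_chain", mets, rxns, sto)
}

#' Generate a bottleneck-with-bypass toy model
#'
#' A source metabolite feeds two parallel branches (capacities `b1`, the
#' gene-associated branch, and `b2`, the bypass) that rejoin before a
#' downstream reaction and sink. The downstream maximum is
#' `min(source_ub, b1 + b2)`; after a factor-`f` knockdown of branch 1 it is
#' `min(source_ub, f*b1 + b2)`, so partial reductions are known in closed
#' form.
#'
#' @param b1,b2 branch capacities (branch 1 carries `gene`).
#' @param source_ub capacity of the source exchange.
#' @param gene gene id attached to branch 1.
#' @return A `metabolic_model` with reactions `EX_in`, `Rknock`, `Rbypass`,
#'   `Rdown`, `EX_out`.
#' @export
make_bypass_model <- function(b1 = 5, b2 = 5, source_ub = 100,
                              gene = "G1") {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_in", "Rknock", "Rbypass", "Rdown", "EX_out"),
    name = c("source", "knocked branch", "bypass branch", "downstream",
             "sink"),
    lower_bound = 0,
    upper_bound = c(source_ub, b1, b2, 1000, 1000),
    gene_rule = c("", gene, "", "", ""),
    subsystem = c("Exchange", "Branch", "Branch", "Downstream", "Exchange"),
    stringsAsFactors = FALSE)
  sto <- list(EX_in = c(A = 1),
              Rknock = c(A = -1, B = 1),
              Rbypass = c(A = -1, B = 1),
              Rdown = c(B = -1, C = 1),
              EX_out = c(C = -1))
  metabolic_model("bypass", mets, rxns, sto)
}

#' Generate a diamond (two unequal parallel routes) toy model
#'
#' `A -> B` directly (capacity `direct_ub`) and `A -> C -> B` (capacity
#' `via_ub` per step), then `B -> sink`. The sink maximum is
#' `direct_ub + via_ub` when the source allows it.
#'
#' @param direct_ub capacity of the one-step route.
#' @param via_ub capacity of each step of the two-step route.
#' @param source_ub source exchange capacity.
#' @return A `metabolic_model`.
#' @export
make_diamond_model <- function(direct_ub = 4, via_ub = 3, source_ub = 1000) {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_in", "Rdirect", "Rvia1", "Rvia2", "Rdemand"),
    name = c("source", "direct", "via step 1", "via step 2", "demand"),
    lower_bound = 0,
    upper_bound = c(source_ub, direct_ub, via_ub, via_ub, 1000),
    gene_rule = "",
    subsystem = c("Exchange", "Core", "Core", "Core", "Exchange"),
    stringsAsFactors = FALSE)
  sto <- list(EX_in = c(A = 1),
              Rdirect = c(A = -1, B = 1),
              Rvia1 = c(A = -1, C = 1),
              Rvia2 = c(C = -1, B = 1),
              Rdemand = c(B = -1))
  metabolic_model("diamond", mets, rxns, sto)
}

#' Toy hepatocyte valine/3-hydroxyisobutyrate pathway model
#'
#' A compartmentalized (extracellular/cytosol/mitochondrion) caricature of
#' hepatic valine catabolism: valine uptake and transport, transamination
#' (BCAT) and the branched-chain ketoacid dehydrogenase complex
#' (BCKDHA/BCKDHB/DBT/DLD), hydrolysis of 3-hydroxyisobutyryl-CoA to 3-HIB
#' by HIBCH (the designed unique bottleneck of the valine branch, upper
#' bound 10 versus 100 elsewhere), 3-HIB export, the HIBADH route to
#' methylmalonate semialdehyde with methylmalonate export, the propanoate
#' branch (propionyl-CoA -> methylmalonyl-CoA -> succinyl-CoA) feeding a
#' minimal TCA loop, an HIBCH-independent glucose -> pyruvate -> acetyl-CoA
#' branch with acetate export, and a fatty-acid uptake/carnitine-shuttle
#' pair with a lumped beta-oxidation step. Cofactors are omitted and every
#' internal reaction converts one metabolite into one metabolite, so all
#' flux maxima follow min-cut arithmetic.
#'
#' Under a 50% HIBCH knockdown every valine-branch and propanoate-branch
#' maximum halves (they are all forced through the bottleneck) while the
#' glucose, TCA-loop and fatty-acid reactions are untouched.
#'
#' @return A `metabolic_model` (deterministic; no randomness).
#' @export
make_valine_pathway_model <- function() {
  met <- function(id, name, comp) c(id, name, comp)
  mets <- as.data.frame(rbind(
    met("val_e", "valine [extracellular]", "e"),
    met("val_c", "valine [cytosol]", "c"),
    met("val_m", "valine [mitochondrion]", "m"),
    met("kiv_m", "3-methyl-2-oxobutanoate [mitochondrion]", "m"),
    met("hibcoa_m", "3-hydroxyisobutyryl-CoA [mitochondrion]", "m"),
    met("hib_m", "3-hydroxyisobutyrate [mitochondrion]", "m"),
    met("hib_c", "3-hydroxyisobutyrate [cytosol]", "c"),
    met("hib_e", "3-hydroxyisobutyrate [extracellular]", "e"),
    met("mms_m", "methylmalonate semialdehyde [mitochondrion]", "m"),
    met("mma_m", "methylmalonate [mitochondrion]", "m"),
    met("mma_e", "methylmalonate [extracellular]", "e"),
    met("ppcoa_m", "propionyl-CoA [mitochondrion]", "m"),
    met("mmcoa_m", "methylmalonyl-CoA [mitochondrion]", "m"),
    met("succoa_m", "succinyl-CoA [mitochondrion]", "m"),
    met("succ_m", "succinate [mitochondrion]", "m"),
    met("mal_m", "malate [mitochondrion]", "m"),
    met("glc_e", "glucose [extracellular]", "e"),
    met("glc_c", "glucose [cytosol]", "c"),
    met("pyr_c", "pyruvate [cytosol]", "c"),
    met("pyr_m", "pyruvate [mitochondrion]", "m"),
    met("accoa_m", "acetyl-CoA [mitochondrion]", "m"),
    met("ac_e", "acetate [extracellular]", "e"),
    met("fa_e", "fatty acid [extracellular]", "e"),
    met("fa_c", "fatty acid [cytosol]", "c"),
    met("facoa_m", "fatty acyl-CoA [mitochondrion]", "m")
  ), stringsAsFactors = FALSE)
  names(mets) <- c("id", "name", "compartment")

  rx <- function(id, name, sto, ub, rule, subsystem, lb = 0) {
    list(id = id, name = name, sto = sto, lb = lb, ub = ub, rule = rule,
         subsystem = subsystem)
  }
  defs <- list(
    rx("EX_val", "valine exchange", c(val_e = 1), 1000, "", "Exchange"),
    rx("VALt", "valine uptake", c(val_e = -1, val_c = 1), 100, "",
       "BCAA metabolism"),
    rx("VALtm", "valine mitochondrial transport",
       c(val_c = -1, val_m = 1), 100, "", "BCAA metabolism"),
    rx("BCAT", "valine transamination", c(val_m = -1, kiv_m = 1), 100,
       "BCAT1 or BCAT2", "BCAA metabolism"),
    rx("BCKDH", "branched-chain ketoacid dehydrogenase (lumped)",
       c(kiv_m = -1, hibcoa_m = 1), 100,
       "BCKDHA and BCKDHB and DBT and DLD", "BCAA metabolism"),
    rx("R_HIBCH", "3-hydroxyisobutyryl-CoA hydrolase",
       c(hibcoa_m = -1, hib_m = 1), 10, "HIBCH", "BCAA metabolism"),
    rx("HIBtm", "3-HIB mitochondrial export", c(hib_m = -1, hib_c = 1),
       100, "", "BCAA metabolism"),
    rx("HIBte", "3-HIB excretion", c(hib_c = -1, hib_e = 1), 100, "",
       "BCAA metabolism"),
    rx("EX_hib", "3-HIB exchange", c(hib_e = -1), 1000, "", "Exchange"),
    rx("HIBADH", "3-HIB dehydrogenase", c(hib_m = -1, mms_m = 1), 100,
       "HIBADH", "BCAA metabolism"),
    rx("MMSDH", "semialdehyde to methylmalonate", c(mms_m = -1, mma_m = 1),
       100, "", "BCAA metabolism"),
    rx("MMAte", "methylmalonate export", c(mma_m = -1, mma_e = 1), 100, "",
       "BCAA metabolism"),
    rx("EX_mma", "methylmalonate exchange", c(mma_e = -1), 1000, "",
       "Exchange"),
    rx("MMS2PPC", "semialdehyde to propionyl-CoA",
       c(mms_m = -1, ppcoa_m = 1), 100, "", "Propanoate metabolism"),
    rx("PCC", "propionyl-CoA carboxylase", c(ppcoa_m = -1, mmcoa_m = 1),
       100, "PCCA and PCCB", "Propanoate metabolism"),
    rx("MUT", "methylmalonyl-CoA mutase", c(mmcoa_m = -1, succoa_m = 1),
       100, "MMUT", "Propanoate metabolism"),
    rx("SUCOAS", "succinyl-CoA synthetase", c(succoa_m = -1, succ_m = 1),
       100, "", "TCA cycle"),
    rx("SDHFH", "succinate to malate (lumped)", c(succ_m = -1, mal_m = 1),
       100, "", "TCA cycle"),
    rx("ME", "malic enzyme", c(mal_m = -1, pyr_m = 1), 100, "",
       "TCA cycle"),
    rx("CSTCA", "citrate synthase + TCA to succinyl-CoA (lumped)",
       c(accoa_m = -1, succoa_m = 1), 100, "", "TCA cycle"),
    rx("EX_glc", "glucose exchange", c(glc_e = 1), 1000, "", "Exchange"),
    rx("GLCt", "glucose uptake", c(glc_e = -1, glc_c = 1), 100, "",
       "Glycolysis"),
    rx("GLYC", "glycolysis (lumped)", c(glc_c = -1, pyr_c = 1), 100, "",
       "Glycolysis"),
    rx("PYRtm", "pyruvate mitochondrial transport",
       c(pyr_c = -1, pyr_m = 1), 100, "", "Glycolysis"),
    rx("PDH", "pyruvate dehydrogenase", c(pyr_m = -1, accoa_m = 1), 100,
       "PDHA1", "Glycolysis"),
    rx("ACOUT", "acetate release (lumped)", c(accoa_m = -1, ac_e = 1), 100,
       "", "Glycolysis"),
    rx("EX_ac", "acetate exchange", c(ac_e = -1), 1000, "", "Exchange"),
    rx("EX_fa", "fatty acid exchange", c(fa_e = 1), 1000, "", "Exchange"),
    rx("FAt", "fatty acid uptake", c(fa_e = -1, fa_c = 1), 100, "",
       "Carnitine shuttle"),
    rx("CPT", "carnitine shuttle", c(fa_c = -1, facoa_m = 1), 100, "CPT1A",
       "Carnitine shuttle"),
    rx("BOX", "beta-oxidation (lumped)", c(facoa_m = -1, accoa_m = 1), 100,
       "ACADM and HADHA", "FA beta-oxidation")
  )
  rxns <- data.frame(
    id = vapply(defs, `[[`, "", "id"),
    name = vapply(defs, `[[`, "", "name"),
    lower_bound = vapply(defs, `[[`, 0, "lb"),
    upper_bound = vapply(defs, `[[`, 0, "ub"),
    gene_rule = vapply(defs, `[[`, "", "rule"),
    subsystem = vapply(defs, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE)
  sto <- stats::setNames(lapply(defs, `[[`, "sto"), rxns$id)
  metabolic_model("valine_3hib_toy", mets, rxns, sto)
}

#' Generate a seeded random metabolic network
#'
#' Builds a connected source-to-sink backbone chain across all metabolites
#' first (so the fixture is never vacuously blocked), then adds random
#' unit-or-double-coefficient internal reactions, random bounds and random
#' gene labels. Identical seeds give bit-identical models. Intended for
#' property fuzzing (containment, identity, determinism), not exact-value
#' tests.
#'
#' @param seed integer seed.
#' @param n_metabolites number of internal metabolites (>= 2).
#' @param n_reactions total reactions including the backbone and its two
#'   exchanges; must be at least `n_metabolites + 1`.
#' @param reversibility_prob probability a random reaction is reversible.
#' @param max_bound largest upper-bound magnitude.
#' @param n_genes size of the gene pool assigned to internal reactions.
#' @return A `metabolic_model`.
#' @export
make_random_network <- function(seed, n_metabolites = 8, n_reactions = 14,
                                reversibility_prob = 0.3, max_bound = 100,
                                n_genes = 4) {
  if (n_metabolites < 2) stop("n_metabolites must be >= 2")
  if (n_reactions < n_metabolites + 1) {
    stop("n_reactions must be at least n_metabolites + 1")
  }
  with_seed(seed, {
    met_ids <- paste0("M", seq_len(n_metabolites))
    mets <- data.frame(id = met_ids, name = met_ids, compartment = "c",
                       stringsAsFactors = FALSE)
    genes <- paste0("G", seq_len(n_genes))
    n_backbone <- n_metabolites - 1
    n_extra <- n_reactions - n_backbone - 2
    ids <- c("EX_in",
             paste0("B", seq_len(n_backbone)),
             if (n_extra > 0) paste0("X", seq_len(n_extra)),
             "EX_out")
    sto <- vector("list", length(ids))
    names(sto) <- ids
    sto[["EX_in"]] <- c(M1 = 1)
    for (i in seq_len(n_backbone)) {
      sto[[paste0("B", i)]] <- stats::setNames(c(-1, 1),
                                               met_ids[c(i, i + 1)])
    }
    sto[["EX_out"]] <- stats::setNames(-1, met_ids[n_metabolites])
    if (n_extra > 0) {
      for (k in seq_len(n_extra)) {
        ns <- sample(1:2, 1); np <- sample(1:2, 1)
        subs <- sample(met_ids, ns)
        prods <- sample(setdiff(met_ids, subs), np)
        coef <- stats::setNames(
          c(-sample(1:2, ns, replace = TRUE),
            sample(1:2, np, replace = TRUE)),
          c(subs, prods))
        sto[[paste0("X", k)]] <- coef
      }
    }
    internal <- !(ids %in% c("EX_in", "EX_out"))
    ub <- round(stats::runif(length(ids), 0.1 * max_bound, max_bound), 3)
    rev <- internal & stats::runif(length(ids)) < reversibility_prob
    lb <- ifelse(rev, -ub, 0)
    ub[!internal] <- max_bound * 10
    lb[!internal] <- 0
    rule <- ifelse(internal, sample(genes, length(ids), replace = TRUE), "")
    subsystem <- ifelse(internal,
                        sample(paste0("Subsystem ", 1:3), length(ids),
                               replace = TRUE),
                        "Exchange")
    rxns <- data.frame(id = ids, name = ids, lower_bound = lb,
                       upper_bound = ub, gene_rule = rule,
                       subsystem = subsystem, stringsAsFactors = FALSE)
    metabolic_model(paste0("random_net_seed", seed), mets, rxns, sto,
                    genes = genes)
  })
}

#' Generate a synthetic conditioned-medium concentration table
#'
#' Emulates targeted metabolite measurements of culture medium before and
#' after a fixed conditioning period: the unconditioned baseline is
#' constant, and each conditioned replicate equals
#' `baseline + rate * duration + N(0, noise_sd)`. Positive truth rates are
#' net appearance (release by cells), negative rates net disappearance
#' (consumption).
#'
#' @param truth_rates named numeric vector, metabolite -> rate in uM/h.
#' @param duration_h conditioning period in hours (default 24).
#' @param noise_sd Gaussian measurement noise on the conditioned
#'   concentration, in uM (default 0).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @param n_replicates replicates per metabolite (default 3).
#' @param group group label column value (default `"control"`).
#' @param baseline_conc unconditioned concentration in uM; recycled over
#'   metabolites. Must keep all conditioned concentrations nonnegative.
#' @return data.frame with columns `metabolite`, `group`, `replicate`,
#'   `conditioned_conc_uM`, `unconditioned_conc_uM`, `duration_h`.
#' @export
make_medium_table <- function(truth_rates, duration_h = 24, noise_sd = 0,
                              seed = 1, n_replicates = 3, group = "control",
                              baseline_conc = 50) {
  stopifnot(duration_h > 0, n_replicates >= 1, noise_sd >= 0)
  if (is.null(names(truth_rates)) || any(!nzchar(names(truth_rates)))) {
    stop("truth_rates must be a named vector (metabolite -> rate)")
  }
  baseline <- rep_len(baseline_conc, length(truth_rates))
  with_seed(seed, {
    rows <- lapply(seq_along(truth_rates), function(i) {
      cond <- baseline[i] + truth_rates[i] * duration_h +
        if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd) else 0
      data.frame(metabolite = names(truth_rates)[i], group = group,
                 replicate = seq_len(n_replicates),
                 conditioned_conc_uM = as.numeric(cond),
                 unconditioned_conc_uM = baseline[i],
                 duration_h = duration_h, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (any(out$conditioned_conc_uM < 0)) {
      stop("negative conditioned concentration; raise baseline_conc")
    }
    out
  })
}
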