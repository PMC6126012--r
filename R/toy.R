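# Toy xylose-fermenting yeast model.
#
# A ~30-reaction three-compartment (cytosol c, mitochondria m, extracellular
# e) network carrying the structural motifs of xylose fermentation in
# Scheffersomyces-like yeasts: the cofactor-split xylose reductase (NADH and
# NADPH routes), strictly NAD+-dependent xylitol dehydrogenase,
# xylulokinase, lumped oxidative and non-oxidative pentose phosphate
# pathway, lumped glycolysis, an ethanol branch, lumped TCA, the electron
# transport chain, the external-NADH-dehydrogenase and glycerol-3-phosphate
# shuttles into the mitochondrial quinone pool, a glutamate-shuttle lump
# acting as a net transhydrogenase (1 NADH + 1 NADPH cytosolic -> 2 NADH
# mitochondrial), and a biomass sink drawing hexose, ATP and NADPH.
#
# Coefficients are chosen for hand-verifiable optima, not biological
# fidelity; pathway lumps keep carbon and redox closed so the line of
# optimality has a closed form (see the package vignette for the
# derivation).

#' Toy-model specification
#'
#' @param oxppp_nadph_yield NADPH produced per hexose entering the oxidative
#'   PPP lump (which also releases one CO2 and returns one pentose).
#' @param atp_per_quinol ATP phosphorylated per quinol oxidised by the ETC
#'   lump (P/O-like yield).
#' @param biomass_g6p,biomass_atp,biomass_nadph biomass demands per unit
#'   growth rate (hexose, ATP, NADPH).
#' @param uptake_atp_cost ATP spent per xylose transported (active uptake).
#' @param maintenance non-growth ATP demand imposed as the lower bound of the
#'   ATP-drain reaction (mmol/gCDW/h).
#' @param shuttles subset of `c("NADHDH", "GLYC3P", "GLU")` to include.
#' @param max_flux bound magnitude standing in for "unconstrained"
#'   (mmol/gCDW/h).
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(oxppp_nadph_yield = 2, atp_per_quinol = 1.5,
                           biomass_g6p = 10, biomass_atp = 100,
                           biomass_nadph = 40, uptake_atp_cost = 1,
                           maintenance = 0,
                           shuttles = c("NADHDH", "GLYC3P", "GLU"),
                           max_flux = 1000) {
  stopifnot(oxppp_nadph_yield > 0, atp_per_quinol > 0,
            all(shuttles %in% c("NADHDH", "GLYC3P", "GLU")))
  structure(list(oxppp_nadph_yield = oxppp_nadph_yield,
                 atp_per_quinol = atp_per_quinol,
                 biomass_g6p = biomass_g6p, biomass_atp = biomass_atp,
                 biomass_nadph = biomass_nadph,
                 uptake_atp_cost = uptake_atp_cost,
                 maintenance = maintenance, shuttles = shuttles,
                 max_flux = max_flux),
            class = "toy_model_spec")
}

#' Build the toy metabolic model
#'
#' @param spec a [toy_model_spec()].
#' @return A [metabolic_model()] with objective `GROWTH`.  Every reaction
#'   carries a one-gene GPR except two isozyme (OR) lumps (glycolysis,
#'   oxidative PPP) and two complex (AND) lumps (TCA, ATP synthase), so GPR
#'   evaluation rules are exercised.  The model errors if the reference
#'   aerobic condition (xylose 5 mmol/gCDW/h, oxygen free) cannot grow,
#'   reporting the blocked objective.
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  M <- spec$max_flux
  mets <- rbind(
    data.frame(id = c("xyl", "o2", "co2", "etoh", "xylt"),
               name = c("D-xylose", "oxygen", "carbon dioxide", "ethanol",
                        "xylitol"),
               compartment = "e", stringsAsFactors = FALSE),
    data.frame(id = c("xyl", "xylt", "xlu", "x5p", "g6p", "pyr", "etoh",
                      "co2", "nad", "nadh", "nadp", "nadph", "atp", "adp",
                      "dhap", "glyc3p"),
               name = c("D-xylose", "xylitol", "D-xylulose",
                        "xylulose 5-phosphate", "glucose 6-phosphate",
                        "pyruvate", "ethanol", "carbon dioxide", "NAD+",
                        "NADH", "NADP+", "NADPH", "ATP", "ADP",
                        "dihydroxyacetone phosphate",
                        "glycerol 3-phosphate"),
               compartment = "c", stringsAsFactors = FALSE),
    data.frame(id = c("o2", "co2", "pyr", "nad", "nadh", "q6", "q6h2"),
               name = c("oxygen", "carbon dioxide", "pyruvate", "NAD+",
                        "NADH", "ubiquinone-6", "ubiquinol-6"),
               compartment = "m", stringsAsFactors = FALSE))

  yN <- spec$oxppp_nadph_yield
  P <- spec$atp_per_quinol
  a <- spec$uptake_atp_cost
  bG <- spec$biomass_g6p
  bA <- spec$biomass_atp
  bN <- spec$biomass_nadph

  rx <- list()
  add <- function(id, eq, lb, ub, gpr = paste0("g", id), subsystem, name = id)
    rx[[length(rx) + 1]] <<- list(id = id, eq = eq, lb = lb, ub = ub,
                                  gpr = gpr, subsystem = subsystem,
                                  name = name)

  # exchanges (export-positive)
  add("EX_XYL", "-1 xyl[e] ->", 0, M, "", "exchange", "xylose exchange")
  add("EX_O2", "-1 o2[e] ->", 0, M, "", "exchange", "oxygen exchange")
  add("EX_CO2", "-1 co2[e] ->", 0, M, "", "exchange", "CO2 exchange")
  add("EX_ETOH", "-1 etoh[e] ->", 0, M, "", "exchange", "ethanol exchange")
  add("EX_XYLT", "-1 xylt[e] ->", 0, M, "", "exchange", "xylitol exchange")

  # transport
  add("XYLt",
      sprintf("-1 xyl[e] + -%s atp[c] -> 1 xyl[c] + %s adp[c]",
              .fmt_num(a), .fmt_num(a)),
      0, M, subsystem = "transport", name = "xylose uptake (active)")
  add("O2t", "-1 o2[e] -> 1 o2[m]", 0, M, subsystem = "transport",
      name = "oxygen diffusion")
  add("CO2t", "-1 co2[c] -> 1 co2[e]", 0, M, subsystem = "transport",
      name = "CO2 export")
  add("CO2tm", "-1 co2[m] -> 1 co2[c]", 0, M, subsystem = "transport",
      name = "mitochondrial CO2 export")
  add("ETOHt", "-1 etoh[c] -> 1 etoh[e]", 0, M, subsystem = "transport",
      name = "ethanol export")
  add("XYLTt", "-1 xylt[c] -> 1 xylt[e]", 0, M, subsystem = "transport",
      name = "xylitol export")
  add("PYRtm", "-1 pyr[c] -> 1 pyr[m]", 0, M, subsystem = "transport",
      name = "pyruvate import")

  # xylose assimilation
  add("XYLR1", "-1 xyl[c] + -1 nadh[c] -> 1 xylt[c] + 1 nad[c]", 0, M,
      gpr = "gXYL1", subsystem = "xylose assimilation",
      name = "xylose reductase (NADH)")
  add("XYLR2", "-1 xyl[c] + -1 nadph[c] -> 1 xylt[c] + 1 nadp[c]", 0, M,
      gpr = "gXYL1", subsystem = "xylose assimilation",
      name = "xylose reductase (NADPH)")
  add("XDH", "-1 xylt[c] + -1 nad[c] <=> 1 xlu[c] + 1 nadh[c]", -M, M,
      gpr = "gXYL2", subsystem = "xylose assimilation",
      name = "xylitol dehydrogenase")
  add("XYLK", "-1 xlu[c] + -1 atp[c] -> 1 x5p[c] + 1 adp[c]", 0, M,
      gpr = "gXYL3", subsystem = "xylose assimilation", name = "xylulokinase")

  # pentose phosphate pathway
  add("NOXPPP", "-6 x5p[c] <=> 5 g6p[c]", -M, M, subsystem = "PPP",
      name = "non-oxidative PPP (lumped)")
  add("OXPPP",
      sprintf("-1 g6p[c] + -%s nadp[c] -> 1 x5p[c] + 1 co2[c] + %s nadph[c]",
              .fmt_num(yN), .fmt_num(yN)),
      0, M, gpr = "gZWF1 or gZWF2", subsystem = "PPP",
      name = "oxidative PPP (lumped)")

  # glycolysis and fermentation
  add("GLYCL",
      "-1 g6p[c] + -2 adp[c] + -2 nad[c] -> 2 pyr[c] + 2 atp[c] + 2 nadh[c]",
      0, M, gpr = "gGLY1 or gGLY2", subsystem = "glycolysis",
      name = "glycolysis (lumped)")
  add("PDC_ADH", "-1 pyr[c] + -1 nadh[c] -> 1 etoh[c] + 1 co2[c] + 1 nad[c]",
      0, M, gpr = "gPDC", subsystem = "fermentation",
      name = "pyruvate decarboxylase + alcohol dehydrogenase")

  # TCA and ETC
  add("TCA",
      "-1 pyr[m] + -4 nad[m] + -1 q6[m] -> 3 co2[m] + 4 nadh[m] + 1 q6h2[m]",
      0, M, gpr = "gTCA1 and gTCA2", subsystem = "TCA",
      name = "pyruvate oxidation via TCA (lumped)")
  add("NADHDHm", "-1 nadh[m] + -1 q6[m] -> 1 nad[m] + 1 q6h2[m]", 0, M,
      gpr = "gNDI", subsystem = "ETC", name = "internal NADH dehydrogenase")
  add("OXPHOS",
      sprintf("-1 q6h2[m] + -0.5 o2[m] + -%s adp[c] -> 1 q6[m] + %s atp[c]",
              .fmt_num(P), .fmt_num(P)),
      0, M, gpr = "gATP1 and gATP2", subsystem = "ETC",
      name = "quinol oxidase + ATP synthase (lumped)")

  # electron shuttles
  if ("NADHDH" %in% spec$shuttles)
    add("NADHDH", "-1 nadh[c] + -1 q6[m] -> 1 nad[c] + 1 q6h2[m]", 0, M,
        gpr = "gNDE", subsystem = "shuttle",
        name = "external NADH dehydrogenase shuttle")
  if ("GLYC3P" %in% spec$shuttles) {
    add("GPD", "-1 nadh[c] + -1 dhap[c] -> 1 nad[c] + 1 glyc3p[c]", 0, M,
        gpr = "gGPD1", subsystem = "shuttle",
        name = "cytosolic glycerol-3-phosphate dehydrogenase")
    add("G3PDm", "-1 glyc3p[c] + -1 q6[m] -> 1 dhap[c] + 1 q6h2[m]", 0, M,
        gpr = "gGUT2", subsystem = "shuttle",
        name = "mitochondrial glycerol-3-phosphate dehydrogenase")
  }
  if ("GLU" %in% spec$shuttles)
    add("GLUSH",
        "-1 nadh[c] + -1 nadph[c] + -2 nad[m] -> 1 nad[c] + 1 nadp[c] + 2 nadh[m]",
        0, M, gpr = "gGLU1", subsystem = "shuttle",
        name = "glutamate shuttle (lumped transhydrogenase)")

  # maintenance and growth
  add("ATPM", "-1 atp[c] -> 1 adp[c]", spec$maintenance, M, gpr = "",
      subsystem = "maintenance", name = "non-growth ATP demand")
  add("GROWTH",
      sprintf("-%s g6p[c] + -%s atp[c] + -%s nadph[c] -> %s adp[c] + %s nadp[c]",
              .fmt_num(bG), .fmt_num(bA), .fmt_num(bN), .fmt_num(bA),
              .fmt_num(bN)),
      0, M, gpr = "", subsystem = "biomass", name = "biomass synthesis")

  reactions <- do.call(rbind, lapply(rx, function(r)
    data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
               subsystem = r$subsystem, stringsAsFactors = FALSE)))
  stoich <- lapply(rx, function(r)
    parse_equation(r$eq, compartments = c("c", "m", "e"))$stoich)
  model <- metabolic_model(mets, reactions, stoich, "GROWTH",
                           compartments = c("c", "m", "e"))

  ref <- solve_fba(model, toy_condition(xylose = 5, our = NULL))
  if (!identical(ref$status, "optimal") || ref$objective <= ZERO_FLUX_TOL)
    stop("toy model specification is infeasible: the reference aerobic ",
         "condition (xylose 5, oxygen free) supports no growth",
         call. = FALSE)
  model
}

#' Reference condition for the toy model
#'
#' @param xylose fixed xylose uptake (mmol/gCDW/h).
#' @param our fixed oxygen uptake rate, or `NULL` to leave oxygen free (any
#'   uptake up to `max_o2`, the aerobic reference).
#' @param xr_ratio optional xylose-reductase cofactor-preference ratio,
#'   imposed as the coupling `v_XYLR2 = ratio * v_XYLR1` (NADPH:NADH).
#' @param max_o2 ceiling used when oxygen is free.
#' @return A [condition_spec()].
#' @export
toy_condition <- function(xylose = 5, our = NULL, xr_ratio = NULL,
                          max_o2 = 1000) {
  cond <- set_uptake(condition_spec(), "EX_XYL", xylose)
  cond <- if (is.null(our)) free_uptake(cond, "EX_O2", max_o2)
          else set_uptake(cond, "EX_O2", our)
  if (!is.null(xr_ratio))
    cond <- add_ratio_coupling(cond, "XYLR2", "XYLR1", xr_ratio)
  cond
}

#' Shuttle definitions for the toy model
#'
#' @return Named list of shuttle definitions (reaction id -> sign) suitable
#'   for [shuttle_flux()]: the net quinol (or mitochondrial NADH) delivery
#'   rate of each shuttle is its terminal reaction's flux.
#' @export
toy_shuttles <- function() {
  list(NADHDH = c(NADHDH = 1),
       GLYC3P = c(G3PDm = 1),
       GLU = c(GLUSH = 1))
}

#' Reactions scored in flux/expression comparisons of the toy model
#'
#' Excludes exchange and transport reactions, reactions without gene
#' association, and the two xylose-reductase routes (one enzyme serves both
#' cofactors, so transcripts cannot separate them).
#'
#' @param model the toy model.
#' @return Character vector of reaction ids.
#' @export
toy_scope <- function(model) {
  r <- model$reactions
  r$id[!(r$subsystem %in% c("exchange", "transport")) &
         nzchar(r$gpr) & !(r$id %in% c("XYLR1", "XYLR2"))]
}
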