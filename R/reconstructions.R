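# Curated core reconstructions of Pelobacter carbinolicus and P. propionicus
# central metabolism, parameterised by the energy contract (EnergyParams) and
# the lumped biomass composition (BiomassSpec).
#
# Stoichiometry is written with explicit protons and charged-species
# formulas, so every internal reaction is elementally and charge balanced;
# proton translocation across the membrane (sulfur reductases, fumarate
# reductase, ATP synthase, symporters/antiporters) moves H+ between the
# cytosolic ("h") and extracellular ("h_e") pools.

#' Energy parameters constructor
#'
#' Defaults are the calibrated P. carbinolicus values: GAM 97.5 mmol ATP/gdw
#' and nGAM 0.844 mmol ATP/gdw/h from the chemostat maintenance regression,
#' H+/2e- of 2 for the hydrogen-dependent sulfur reductase (SRE) and 1 for
#' the NADPH-dependent one (SRE2) from the yield-ratio grid scan, and 3
#' H+/ATP for the ATP synthase (a conventional value; the translocation
#' stoichiometry of the synthase is not constrained by the data and is
#' exposed here).
#'
#' @param gam growth-associated maintenance (mmol ATP/gdw).
#' @param ngam non-growth-associated maintenance (mmol ATP/gdw/h); use 2.80
#'   for the P. propionicus model.
#' @param sreHPer2e,sre2HPer2e sulfur-reductase H+/2e- ratios (1 or 2).
#' @param atpSynthaseHPerAtp ATP synthase H+/ATP.
#' @return an \linkS4class{EnergyParams}.
#' @export
energyParams <- function(gam = 97.5, ngam = 0.844, sreHPer2e = 2,
                         sre2HPer2e = 1, atpSynthaseHPerAtp = 3) {
  new("EnergyParams", gam = gam, ngam = ngam, sreHPer2e = sreHPer2e,
      sre2HPer2e = sre2HPer2e, atpSynthaseHPerAtp = atpSynthaseHPerAtp)
}

#' Lumped biomass composition constructor
#'
#' The published biomass composition behind the source reconstructions is
#' not available, so biomass demand is lumped into its carbon/electron/
#' nitrogen/ATP channels: acetyl-CoA (default 21 mmol/gdw, i.e. about 42
#' mmol C/gdw), NADPH (8 mmol/gdw) and ammonium (10 mmol/gdw), with the GAM
#' ATP taken from [energyParams()]. The defaults are order-of-magnitude
#' standards for bacterial biomass; [calibrateBiomass()] tunes them against
#' observed flux ratios.
#'
#' @param accoa,nadph,nh4 coefficients in mmol per gdw biomass.
#' @return a \linkS4class{BiomassSpec}.
#' @export
biomassSpec <- function(accoa = 21, nadph = 8, nh4 = 10) {
  new("BiomassSpec", accoa = accoa, nadph = nadph, nh4 = nh4)
}

# ---- metabolite registry ---------------------------------------------------

coreMet <- function(id, name, formula, charge, compartment) {
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = charge, stringsAsFactors = FALSE)
}

coreMetabolites <- function(species) {
  m <- rbind(
    coreMet("h2o",   "Water", "H2O", 0, "c"),
    coreMet("h",     "Proton (cytosol)", "H", 1, "c"),
    coreMet("atp",   "ATP", "C10H12N5O13P3", -4, "c"),
    coreMet("adp",   "ADP", "C10H12N5O10P2", -3, "c"),
    coreMet("pi",    "Orthophosphate", "HPO4", -2, "c"),
    coreMet("nad",   "NAD+", "C21H26N7O14P2", -1, "c"),
    coreMet("nadh",  "NADH", "C21H27N7O14P2", -2, "c"),
    coreMet("nadp",  "NADP+", "C21H25N7O17P3", -3, "c"),
    coreMet("nadph", "NADPH", "C21H26N7O17P3", -4, "c"),
    coreMet("coa",   "Coenzyme A", "C21H32N7O16P3S", -4, "c"),
    coreMet("accoa", "Acetyl-CoA", "C23H34N7O17P3S", -4, "c"),
    coreMet("actp",  "Acetyl phosphate", "C2H3O5P", -2, "c"),
    coreMet("ac",    "Acetate", "C2H3O2", -1, "c"),
    coreMet("acald", "Acetaldehyde", "C2H4O", 0, "c"),
    coreMet("etoh",  "Ethanol", "C2H6O", 0, "c"),
    coreMet("actn",  "Acetoin", "C4H8O2", 0, "c"),
    coreMet("btd",   "2,3-Butanediol", "C4H10O2", 0, "c"),
    coreMet("h2",    "Hydrogen", "H2", 0, "c"),
    coreMet("co2",   "Carbon dioxide", "CO2", 0, "c"),
    coreMet("pyr",   "Pyruvate", "C3H3O3", -1, "c"),
    coreMet("nh4",   "Ammonium", "H4N", 1, "c"),
    coreMet("so4",   "Sulfate", "O4S", -2, "c"),
    coreMet("oaa",   "Oxaloacetate", "C4H2O5", -2, "c"),
    coreMet("mal",   "L-Malate", "C4H4O5", -2, "c"),
    coreMet("fum",   "Fumarate", "C4H2O4", -2, "c"),
    coreMet("succ",  "Succinate", "C4H4O4", -2, "c"),
    coreMet("succoa", "Succinyl-CoA", "C25H35N7O19P3S", -5, "c"),
    coreMet("cit",   "Citrate", "C6H5O7", -3, "c"),
    coreMet("icit",  "Isocitrate", "C6H5O7", -3, "c"),
    coreMet("akg",   "2-Oxoglutarate", "C5H4O5", -2, "c"),
    coreMet("mqn",   "Menaquinone", "C46H64O2", 0, "c"),
    coreMet("mql",   "Menaquinol", "C46H66O2", 0, "c"),
    # extracellular
    coreMet("actn_e", "Acetoin (extracellular)", "C4H8O2", 0, "e"),
    coreMet("btd_e",  "2,3-Butanediol (extracellular)", "C4H10O2", 0, "e"),
    coreMet("etoh_e", "Ethanol (extracellular)", "C2H6O", 0, "e"),
    coreMet("ac_e",   "Acetate (extracellular)", "C2H3O2", -1, "e"),
    coreMet("h2_e",   "Hydrogen (extracellular)", "H2", 0, "e"),
    coreMet("co2_e",  "Carbon dioxide (extracellular)", "CO2", 0, "e"),
    coreMet("h2o_e",  "Water (extracellular)", "H2O", 0, "e"),
    coreMet("h_e",    "Proton (extracellular)", "H", 1, "e"),
    coreMet("nh4_e",  "Ammonium (extracellular)", "H4N", 1, "e"),
    coreMet("pi_e",   "Orthophosphate (extracellular)", "HPO4", -2, "e"),
    coreMet("so4_e",  "Sulfate (extracellular)", "O4S", -2, "e"),
    coreMet("k_e",    "Potassium", "K", 1, "e"),
    coreMet("mg2_e",  "Magnesium", "Mg", 2, "e"),
    coreMet("fe3_e",  "Fe(III)", "Fe", 3, "e"),
    coreMet("fe2_e",  "Fe(II)", "Fe", 2, "e"),
    coreMet("s0_e",   "Elemental sulfur", "S", 0, "e"),
    coreMet("hs_e",   "Hydrogen sulfide", "HS", -1, "e")
  )
  if (species == "pcar") {
    m <- rbind(m,
      coreMet("eg",    "Ethylene glycol", "C2H6O2", 0, "c"),
      coreMet("eg_e",  "Ethylene glycol (extracellular)", "C2H6O2", 0, "e"),
      coreMet("for",   "Formate", "CHO2", -1, "c"),
      coreMet("for_e", "Formate (extracellular)", "CHO2", -1, "e"))
  } else {
    m <- rbind(m,
      coreMet("lac",    "L-Lactate", "C3H5O3", -1, "c"),
      coreMet("lac_e",  "L-Lactate (extracellular)", "C3H5O3", -1, "e"),
      coreMet("ppa",    "Propionate", "C3H5O2", -1, "c"),
      coreMet("ppa_e",  "Propionate (extracellular)", "C3H5O2", -1, "e"),
      coreMet("ppcoa",  "Propionyl-CoA", "C24H36N7O17P3S", -4, "c"),
      coreMet("mmcoa",  "(S)-Methylmalonyl-CoA", "C25H35N7O19P3S", -5, "c"),
      coreMet("ppoh",   "1-Propanol", "C3H8O", 0, "c"),
      coreMet("ppoh_e", "1-Propanol (extracellular)", "C3H8O", 0, "e"),
      coreMet("ppal",   "Propionaldehyde", "C3H6O", 0, "c"),
      coreMet("btoh",   "1-Butanol", "C4H10O", 0, "c"),
      coreMet("btoh_e", "1-Butanol (extracellular)", "C4H10O", 0, "e"),
      coreMet("btal",   "Butyraldehyde", "C4H8O", 0, "c"),
      coreMet("btcoa",  "Butyryl-CoA", "C25H38N7O17P3S", -4, "c"),
      coreMet("but",    "Butyrate", "C4H7O2", -1, "c"),
      coreMet("but_e",  "Butyrate (extracellular)", "C4H7O2", -1, "e"))
  }
  m
}

# ---- reaction assembly -----------------------------------------------------

# internal: accumulate reactions as (row, stoich) pairs
rxnAccumulator <- function() {
  rows <- list()
  st <- list()
  add <- function(id, name, stoich, lower = 0, upper = Inf, gpr = "",
                  subsystem = "Central Metabolism") {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = name, lower = lower, upper = upper, gpr = gpr,
      subsystem = subsystem, stringsAsFactors = FALSE)
    st[[length(st) + 1L]] <<- stoich
  }
  list(add = add,
       reactions = function() do.call(rbind, rows),
       stoich = function() st)
}

s_ <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)), all(nzchar(names(v))))
  v
}

addExchange <- function(acc, met) {
  acc$add(paste0("EX_", met), paste0("Exchange of ", met),
          s_(stats::setNames(-1, met)), lower = -1000, upper = 1000,
          subsystem = "Other")
}

# reactions common to both species
addSharedCore <- function(acc, ep, species) {
  REV <- c(-1000, 1000)
  n1 <- ep@sreHPer2e
  n2 <- ep@sre2HPer2e
  m <- ep@atpSynthaseHPerAtp

  # exchanges
  for (met in c("actn_e", "btd_e", "etoh_e", "ac_e", "h2_e", "co2_e",
                "h2o_e", "h_e", "nh4_e", "pi_e", "so4_e", "k_e", "mg2_e",
                "fe3_e", "fe2_e", "s0_e", "hs_e")) {
    addExchange(acc, met)
  }

  # transport: neutral solutes by energy-free reversible diffusion
  diff2 <- function(id, eMet, cMet, name) {
    acc$add(id, name, s_(stats::setNames(c(-1, 1), c(eMet, cMet))),
            lower = -1000, upper = 1000, subsystem = "Transport")
  }
  diff2("ACTNt", "actn_e", "actn", "Acetoin diffusion")
  diff2("BTDt", "btd_e", "btd", "2,3-butanediol diffusion")
  diff2("ETOHt", "etoh_e", "etoh", "Ethanol diffusion")
  diff2("H2t", "h2_e", "h2", "Hydrogen diffusion")
  diff2("CO2t", "co2_e", "co2", "CO2 diffusion")
  diff2("H2Ot", "h2o_e", "h2o", "Water diffusion")
  diff2("NH4t", "nh4_e", "nh4", "Ammonium uptake (NH3 diffusion)")
  acc$add("ACt", "Acetate/proton symport",
          s_(ac_e = -1, h_e = -1, ac = 1, h = 1),
          lower = -1000, upper = 1000, subsystem = "Transport")
  acc$add("PIt", "Phosphate/proton symport",
          s_(pi_e = -1, h_e = -1, pi = 1, h = 1),
          lower = -1000, upper = 1000, subsystem = "Transport")
  acc$add("SO4t", "Sulfate/proton symport",
          s_(so4_e = -1, h_e = -1, so4 = 1, h = 1),
          lower = -1000, upper = 1000, subsystem = "Transport",
          gpr = if (species == "pcar") "Pcar_0676" else "")

  # acetoin / butanediol fermentation backbone
  acc$add("BTDD", "2,3-butanediol dehydrogenase",
          s_(btd = -1, nad = -1, actn = 1, nadh = 1, h = 1))
  acc$add("ACTNOR", "Acetoin:DCPIP oxidoreductase (acetoin dehydrogenase)",
          s_(actn = -1, coa = -1, nad = -1,
             acald = 1, accoa = 1, nadh = 1, h = 1),
          gpr = if (species == "pcar")
            "Pcar_0343 & Pcar_0344 & Pcar_0345 & Pcar_0347"
          else "Ppro_1131 & Ppro_1132 & Ppro_1133 & Ppro_1137")
  acc$add("ALCD2x", "Alcohol dehydrogenase (ethanol:NAD)",
          s_(etoh = -1, nad = -1, acald = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000,
          gpr = if (species == "pcar") "Pcar_0251 or Pcar_0255" else "")
  acc$add("ACALD", "Acetaldehyde-CoA dehydrogenase (acylating)",
          s_(acald = -1, coa = -1, nad = -1, accoa = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000,
          gpr = if (species == "pcar") "Pcar_2758"
          else "Ppro_0899 or Ppro_1923")
  acc$add("PTA", "Phosphate acetyltransferase",
          s_(accoa = -1, pi = -1, actp = 1, coa = 1),
          lower = -1000, upper = 1000,
          gpr = if (species == "pcar") "Pcar_2542" else "")
  if (species == "pcar") {
    # isozyme duplicate (Pcar_2850), weakly expressed during acetoin growth
    acc$add("PTA2", "Phosphate acetyltransferase (isozyme)",
            s_(accoa = -1, pi = -1, actp = 1, coa = 1),
            lower = -1000, upper = 1000, gpr = "Pcar_2850")
  }
  acc$add("ACK", "Acetate kinase",
          s_(actp = -1, adp = -1, ac = 1, atp = 1),
          lower = -1000, upper = 1000,
          gpr = if (species == "pcar") "Pcar_2543" else "")

  # anaplerosis / pyruvate node
  acc$add("PYRS", "Pyruvate synthase (acetyl-CoA carboxylation, NADH-coupled)",
          s_(accoa = -1, co2 = -1, nadh = -1, pyr = 1, coa = 1, nad = 1),
          lower = -1000, upper = 1000)
  acc$add("PC", "Pyruvate carboxylase",
          s_(pyr = -1, co2 = -1, atp = -1, h2o = -1,
             oaa = 1, adp = 1, pi = 1, h = 2))

  # TCA cycle; succinate oxidation runs only into the menaquinone pool,
  # which has no reoxidation route (no quinol -> S0 coupling)
  acc$add("CS", "Citrate synthase",
          s_(accoa = -1, oaa = -1, h2o = -1, cit = 1, coa = 1, h = 1))
  acc$add("ACONT", "Aconitase", s_(cit = -1, icit = 1),
          lower = -1000, upper = 1000)
  acc$add("ICDHy", "Isocitrate dehydrogenase (NADP)",
          s_(icit = -1, nadp = -1, akg = 1, co2 = 1, nadph = 1),
          lower = -1000, upper = 1000)
  acc$add("AKGD", "2-oxoglutarate dehydrogenase",
          s_(akg = -1, coa = -1, nad = -1, succoa = 1, co2 = 1, nadh = 1))
  acc$add("SUCOAS", "Succinyl-CoA synthetase",
          s_(succoa = -1, adp = -1, pi = -1, succ = 1, atp = 1, coa = 1),
          lower = -1000, upper = 1000)
  acc$add("SUCDmk", "Succinate dehydrogenase (menaquinone)",
          s_(succ = -1, mqn = -1, fum = 1, mql = 1))
  acc$add("FUM", "Fumarase", s_(fum = -1, h2o = -1, mal = 1),
          lower = -1000, upper = 1000)
  acc$add("MDH", "Malate dehydrogenase",
          s_(mal = -1, nad = -1, oaa = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)

  # redox / energy metabolism
  acc$add("HYDA", "NAD-linked hydrogenase",
          s_(nadh = -1, h = -1, nad = 1, h2 = 1),
          lower = -1000, upper = 1000, subsystem = "Energy Metabolism")
  acc$add("THD", "Transhydrogenase",
          s_(nadh = -1, nadp = -1, nad = 1, nadph = 1),
          lower = -1000, upper = 1000, subsystem = "Energy Metabolism")
  acc$add("SRE", "Sulfur reductase (hydrogen-dependent)",
          s_(h2 = -1, s0_e = -1, h = -n1,
             hs_e = 1, h_e = n1 + 1),
          subsystem = "Energy Metabolism")
  acc$add("SRE2", "Sulfur reductase (NADPH-dependent)",
          s_(nadph = -1, s0_e = -1, h = -n2,
             nadp = 1, hs_e = 1, h_e = n2),
          subsystem = "Energy Metabolism")
  acc$add("FE3Rs", "Extracellular nonenzymatic Fe(III) reduction by sulfide",
          s_(fe3_e = -2, hs_e = -1, fe2_e = 2, s0_e = 1, h_e = 1),
          subsystem = "Energy Metabolism")
  acc$add("ATPS", "ATP synthase",
          s_(adp = -1, pi = -1, h_e = -m, atp = 1, h2o = 1, h = m - 1),
          lower = -1000, upper = 1000, subsystem = "Energy Metabolism")
  acc$add("ATPM", "ATP maintenance requirement",
          s_(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
          lower = ep@ngam, upper = 1000, subsystem = "Energy Metabolism")
  invisible(acc)
}

addBiomass <- function(acc, ep, bs) {
  g <- unname(ep@gam)
  bs@accoa <- unname(bs@accoa)
  bs@nadph <- unname(bs@nadph)
  bs@nh4 <- unname(bs@nh4)
  acc$add("BIOMASS", "Lumped biomass demand",
          s_(accoa = -bs@accoa, nadph = -bs@nadph, nh4 = -bs@nh4,
             atp = -g, h2o = -g,
             coa = bs@accoa, nadp = bs@nadph, adp = g, pi = g, h = g),
          lower = 0, upper = 1000, subsystem = "Other")
  invisible(acc)
}

#' Build the P. carbinolicus core model
#'
#' Programmatic reconstruction of P. carbinolicus central fermentative and
#' respiratory metabolism: acetoin cleavage to acetaldehyde + acetyl-CoA,
#' 2,3-butanediol and ethylene glycol utilisation, substrate-level ATP via
#' phosphate acetyltransferase / acetate kinase, pyruvate formate lyase +
#' formate dehydrogenase, the full TCA cycle with succinate oxidation
#' dead-ending in a menaquinone pool (no quinol-to-sulfur route), the two
#' sulfur reductases (SRE, hydrogen-dependent; SRE2, NADPH-dependent) with
#' configurable H+/2e- translocation, the extracellular nonenzymatic
#' sulfide-shuttle Fe(III) reduction (FE3Rs: 2 Fe3+ + HS- -> 2 Fe2+ + S0 +
#' H+), ATP synthase and the lumped biomass demand.
#'
#' @param ep an \linkS4class{EnergyParams} (defaults are the calibrated
#'   P. carbinolicus values).
#' @param bs a \linkS4class{BiomassSpec}.
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
buildPcarCore <- function(ep = energyParams(), bs = biomassSpec()) {
  acc <- rxnAccumulator()
  addSharedCore(acc, ep, "pcar")
  for (met in c("eg_e", "for_e")) addExchange(acc, met)
  acc$add("EGt", "Ethylene glycol diffusion",
          s_(eg_e = -1, eg = 1), lower = -1000, upper = 1000,
          subsystem = "Transport")
  # "for" (formate) is a reserved word in R, so these vectors use setNames
  acc$add("FORt", "Formate/proton symport",
          stats::setNames(c(-1, -1, 1, 1), c("for_e", "h_e", "for", "h")),
          lower = -1000, upper = 1000, subsystem = "Transport")
  acc$add("EGDH", "Ethylene glycol dehydratase",
          s_(eg = -1, acald = 1, h2o = 1))
  acc$add("PFL", "Pyruvate formate lyase",
          stats::setNames(c(-1, -1, 1, 1), c("pyr", "coa", "accoa", "for")))
  acc$add("FDH", "Formate dehydrogenase (NAD)",
          stats::setNames(c(-1, -1, 1, 1), c("for", "nad", "co2", "nadh")))
  addBiomass(acc, ep, bs)
  makeModel("pcar_core", "Pelobacter carbinolicus",
            coreMetabolites("pcar"), acc$reactions(), acc$stoich(),
            biomassReaction = "BIOMASS", atpmReaction = "ATPM",
            biomassGAM = ep@gam)
}

#' Build the P. propionicus core model
#'
#' The shared Pelobacter core (without the P. carbinolicus-unique ethylene
#' glycol dehydratase and pyruvate formate lyase / formate dehydrogenase)
#' plus the methylmalonyl-CoA-dependent propionate pathway: lactate
#' dehydrogenase with a lactate/proton antiporter (energy conservation in
#' lactate uptake; symport and diffusion variants available for comparison),
#' ferredoxin-type reductive carboxylation of acetyl-CoA to pyruvate carried
#' NADH-coupled and ATP-free, malate dehydrogenase/fumarase shared with the
#' TCA core, a proton-translocating membrane fumarate reductase,
#' propionyl-CoA:succinate CoA-transferase, lumped methylmalonyl-CoA mutase
#' + epimerase, methylmalonyl-CoA:pyruvate transcarboxylase, succinyl-
#' CoA:acetate CoA-transferase (ATP-neutral acetate activation, required for
#' the acetate-consuming propanol/butanol fermentations), propanol/butanol
#' oxidation routes with butyrate export, and citrate lyase (shipped closed;
#' its physiological role is unresolved).
#'
#' @param ep an \linkS4class{EnergyParams}; the P. propionicus nGAM is 2.80
#'   mmol ATP/gdw/h.
#' @param bs a \linkS4class{BiomassSpec}.
#' @param lactateTransport "antiport" (default), "symport" or "diffusion".
#' @param frdHPer2e protons translocated per 2e- by the membrane fumarate
#'   reductase (default 2).
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
buildPproCore <- function(ep = energyParams(ngam = 2.80), bs = biomassSpec(),
                          lactateTransport = c("antiport", "symport",
                                               "diffusion"),
                          frdHPer2e = 2) {
  lactateTransport <- match.arg(lactateTransport)
  k <- frdHPer2e
  acc <- rxnAccumulator()
  addSharedCore(acc, ep, "ppro")
  for (met in c("lac_e", "ppa_e", "ppoh_e", "btoh_e", "but_e")) {
    addExchange(acc, met)
  }
  if (lactateTransport == "antiport") {
    acc$add("LACt", "Lactate/proton antiport",
            s_(lac_e = -1, h = -1, lac = 1, h_e = 1),
            lower = -1000, upper = 1000, subsystem = "Transport")
  } else if (lactateTransport == "symport") {
    acc$add("LACt", "Lactate/proton symport",
            s_(lac_e = -1, h_e = -1, lac = 1, h = 1),
            lower = -1000, upper = 1000, subsystem = "Transport")
  } else {
    acc$add("LACt", "Lactate diffusion",
            s_(lac_e = -1, lac = 1),
            lower = -1000, upper = 1000, subsystem = "Transport")
  }
  acc$add("LDH_L", "L-lactate dehydrogenase",
          s_(lac = -1, nad = -1, pyr = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)
  acc$add("FRDH", "Membrane fumarate reductase (proton-translocating)",
          s_(fum = -1, nadh = -1, h = -(1 + k),
             succ = 1, nad = 1, h_e = k),
          subsystem = "Energy Metabolism")
  acc$add("PCOATA", "Propionyl-CoA:succinate CoA-transferase",
          s_(ppcoa = -1, succ = -1, ppa = 1, succoa = 1),
          lower = -1000, upper = 1000)
  acc$add("MMM", "Methylmalonyl-CoA mutase + epimerase (lumped)",
          s_(succoa = -1, mmcoa = 1),
          lower = -1000, upper = 1000, gpr = "Ppro_1367 & Ppro_1368")
  acc$add("MMCOAT", "Methylmalonyl-CoA:pyruvate transcarboxylase",
          s_(mmcoa = -1, pyr = -1, ppcoa = 1, oaa = 1),
          lower = -1000, upper = 1000)
  acc$add("ASCT", "Succinyl-CoA:acetate CoA-transferase",
          s_(ac = -1, succoa = -1, accoa = 1, succ = 1),
          lower = -1000, upper = 1000)
  acc$add("PPAt", "Propionate/proton symport",
          s_(ppa = -1, h = -1, ppa_e = 1, h_e = 1),
          lower = -1000, upper = 1000, subsystem = "Transport")
  acc$add("PPOHt", "1-propanol diffusion",
          s_(ppoh_e = -1, ppoh = 1), lower = -1000, upper = 1000,
          subsystem = "Transport")
  acc$add("BTOHt", "1-butanol diffusion",
          s_(btoh_e = -1, btoh = 1), lower = -1000, upper = 1000,
          subsystem = "Transport")
  acc$add("PPOHDH", "Propanol dehydrogenase",
          s_(ppoh = -1, nad = -1, ppal = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)
  acc$add("PPALDH", "Propionaldehyde-CoA dehydrogenase",
          s_(ppal = -1, coa = -1, nad = -1, ppcoa = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)
  acc$add("BTOHDH", "Butanol dehydrogenase",
          s_(btoh = -1, nad = -1, btal = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)
  acc$add("BTALDH", "Butyraldehyde-CoA dehydrogenase",
          s_(btal = -1, coa = -1, nad = -1, btcoa = 1, nadh = 1, h = 1),
          lower = -1000, upper = 1000)
  acc$add("BTCOAT", "Butyryl-CoA:acetate CoA-transferase",
          s_(btcoa = -1, ac = -1, but = 1, accoa = 1),
          lower = -1000, upper = 1000)
  acc$add("BUTt", "Butyrate/proton symport",
          s_(but = -1, h = -1, but_e = 1, h_e = 1),
          lower = -1000, upper = 1000, subsystem = "Transport")
  # citrate lyase: unique to P. propionicus, physiological role unclear;
  # shipped closed
  acc$add("CITL", "Citrate lyase (closed by default)",
          s_(cit = -1, oaa = 1, ac = 1), lower = 0, upper = 0)
  addBiomass(acc, ep, bs)
  makeModel("ppro_core", "Pelobacter propionicus",
            coreMetabolites("ppro"), acc$reactions(), acc$stoich(),
            biomassReaction = "BIOMASS", atpmReaction = "ATPM",
            biomassGAM = ep@gam)
}

#' Build a species core model by label
#'
#' @param species "pcar" or "ppro".
#' @param ep,bs energy parameters and biomass spec.
#' @param ... passed to the species builder.
#' @return a \linkS4class{MetabolicModel}.
#' @export
buildCoreModel <- function(species = c("pcar", "ppro"),
                           ep = NULL, bs = biomassSpec(), ...) {
  species <- match.arg(species)
  if (species == "pcar") {
    buildPcarCore(ep = if (is.null(ep)) energyParams() else ep, bs = bs)
  } else {
    buildPproCore(ep = if (is.null(ep)) energyParams(ngam = 2.80) else ep,
                  bs = bs, ...)
  }
}
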