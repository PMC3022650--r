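# Shared fixtures, built once per test run.

# a linear chain: EX_a (uptake) -> transport -> conversion -> EX_b
chainModel <- function(coefA = 1, coefB = 1, cap = 10) {
  mets <- data.frame(
    id = c("a", "b", "a_e", "b_e"),
    name = c("a", "b", "a ext", "b ext"),
    compartment = c("c", "c", "e", "e"),
    formula = NA_character_, charge = NA_real_, stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_a_e", "Ta", "R1", "Tb", "EX_b_e"),
    name = c("exchange a", "transport a", "a to b", "transport b",
             "exchange b"),
    lower = c(-cap, 0, 0, 0, 0),
    upper = c(0, 5 * cap, 5 * cap, 5 * cap, 5 * cap),
    gpr = "", subsystem = "Other", stringsAsFactors = FALSE)
  st <- list(c(a_e = -1), c(a_e = -1, a = 1), c(a = -coefA, b = coefB),
             c(b = -1, b_e = 1), c(b_e = -1))
  makeModel("chain", "toy chain", mets, rxns, st,
            biomassReaction = "EX_b_e", atpmReaction = "Tb", check = FALSE)
}

# fermentation condition: H2 / formate secretion closed
fermCondition <- function(model, objective = biomassReaction(model), ...) {
  makeCondition(objective,
                closeReactions = intersect(c("EX_h2_e", "EX_for_e"),
                                           model@reactions$id), ...)
}

pcarDefault <- buildPcarCore()
pproDefault <- buildPproCore()
epPpro <- energyParams(ngam = 2.80)
calibBS <- calibratedBiomassSpec()
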