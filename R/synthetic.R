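# Seeded synthetic-data generators: chemostat observations carrying the
# maintenance structure qATP = GAM*mu + nGAM, growth-yield records, and
# random toy stoichiometric networks whose optimum is computed by
# brute-force basic-solution enumeration (the LP oracle used in tests).

#' Generator configuration
#'
#' @param seed integer random seed; fixed seed means fully reproducible
#'   output.
#' @param dilutionRates chemostat dilution rates (1/h); the experimental
#'   design spanned 0.03-0.06 1/h.
#' @param noiseSd multiplicative Gaussian noise standard deviation as a
#'   fraction of each flux (0 = noiseless); draws are truncated at +/- 3 sd
#'   so fluxes cannot flip sign.
#' @return list of class "GeneratorConfig".
#' @export
generatorConfig <- function(seed = 1L,
                            dilutionRates = c(0.03, 0.04, 0.05, 0.06),
                            noiseSd = 0) {
  stopifnot(noiseSd >= 0, all(dilutionRates > 0))
  structure(list(seed = as.integer(seed), dilutionRates = dilutionRates,
                 noiseSd = noiseSd), class = "GeneratorConfig")
}

# truncated multiplicative noise factor
noiseFactor <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  z <- stats::rnorm(n)
  z <- pmax(pmin(z, 3), -3)
  1 + sd * z
}

#' Generate synthetic chemostat observations
#'
#' For each dilution rate, solves the minimal-substrate problem on the
#' given model (acetoin fermentation by default: H2 and formate secretion
#' closed, growth fixed at the dilution rate, the embedded GAM/nGAM
#' determining the ATP demand), records the substrate uptake and acetate
#' secretion fluxes, and applies seeded truncated multiplicative noise.
#'
#' @param model a \linkS4class{MetabolicModel} with the energy parameters of
#'   interest embedded (GAM in the biomass reaction, nGAM as the ATPM lower
#'   bound).
#' @param cfg a [generatorConfig()].
#' @param substrate substrate extracellular metabolite id (default acetoin).
#' @return data.frame with columns \code{mu} and the two measured exchange
#'   fluxes (substrate uptake negative, acetate secretion positive),
#'   suitable for [fitMaintenance()].
#' @export
genChemostatObs <- function(model, cfg = generatorConfig(),
                            substrate = "actn_e") {
  rid <- exchangeIdFor(model, substrate)
  closes <- intersect(c("EX_h2_e", "EX_for_e"), model@reactions$id)
  rows <- lapply(cfg$dilutionRates, function(mu) {
    cond <- makeCondition(rid, closeReactions = closes)
    sol <- minSubstrateAtGrowth(model, substrate, mu, condition = cond)
    if (solverStatus(sol) != "optimal") {
      stop("model infeasible at dilution rate ", mu)
    }
    fx <- fluxes(sol)
    data.frame(mu = mu, up = fx[[rid]], ac = fx[["EX_ac_e"]])
  })
  obs <- do.call(rbind, rows)
  set.seed(cfg$seed)
  obs$up <- obs$up * noiseFactor(nrow(obs), cfg$noiseSd)
  obs$ac <- obs$ac * noiseFactor(nrow(obs), cfg$noiseSd)
  names(obs) <- c("mu", rid, "EX_ac_e")
  obs
}

#' Generate synthetic growth-yield records
#'
#' Simulates fixed-growth fermentative growth on each substrate (minimal
#' substrate uptake at the given growth rate) and converts the uptake flux
#' to a molar biomass yield mu/uptake; optional seeded noise as in
#' [genChemostatObs()].
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param substrates character vector of extracellular metabolite ids.
#' @param mu growth rate fixed in every simulation (1/h).
#' @param cfg a [generatorConfig()] (its dilution rates are not used here).
#' @return data.frame with columns \code{substrate}, \code{mu},
#'   \code{yield}, suitable for [estimateNgamFromYields()].
#' @export
genYieldRecords <- function(model, substrates, mu = 0.144,
                            cfg = generatorConfig()) {
  if (!length(substrates)) {
    return(data.frame(substrate = character(0), mu = numeric(0),
                      yield = numeric(0)))
  }
  closes <- intersect(c("EX_h2_e", "EX_for_e"), model@reactions$id)
  rows <- lapply(substrates, function(s) {
    rid <- exchangeIdFor(model, s)
    cond <- makeCondition(rid, closeReactions = closes)
    sol <- minSubstrateAtGrowth(model, s, mu, condition = cond)
    if (solverStatus(sol) != "optimal") {
      stop("substrate ", s, " cannot support growth rate ", mu)
    }
    uptake <- -fluxes(sol)[[rid]]
    data.frame(substrate = s, mu = mu, yield = mu / uptake,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  set.seed(cfg$seed)
  out$yield <- out$yield * noiseFactor(nrow(out), cfg$noiseSd)
  out
}

# ---- toy networks with enumerated optima -----------------------------------

#' Brute-force LP optimum by basic-solution enumeration
#'
#' Independent oracle for small bounded LPs: enumerates every basic
#' solution (each choice of rank(S) basic columns with the remaining
#' variables at one of their finite bounds), checks feasibility, and
#' returns the best objective value. All bounds must be finite.
#'
#' @param obj objective vector (maximised).
#' @param S constraint matrix (S x = 0).
#' @param lb,ub finite bound vectors.
#' @return list: \code{objective} (NA if infeasible), \code{x}.
#' @export
enumerateLPOptimum <- function(obj, S, lb, ub) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  best <- NULL
  bestX <- NULL
  consider <- function(x) {
    if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) return()
    if (max(abs(S %*% x)) > 1e-6 * max(1, max(abs(x)))) return()
    v <- sum(obj * x)
    if (is.null(best) || v > best) {
      best <<- v
      bestX <<- x
    }
  }
  if (r == 0L) {
    x <- ifelse(obj > 0, ub, lb)
    consider(x)
  } else {
    combs <- utils::combn(n, r)
    for (ci in seq_len(ncol(combs))) {
      B <- combs[, ci]
      SB <- S[, B, drop = FALSE]
      qrB <- qr(SB)
      if (qrB$rank < r) next
      N <- setdiff(seq_len(n), B)
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
      for (gi in seq_len(nrow(grid))) {
        x <- numeric(n)
        xN <- ifelse(unlist(grid[gi, ]), ub[N], lb[N])
        x[N] <- xN
        rhs <- -S[, N, drop = FALSE] %*% xN
        xB <- tryCatch(qr.coef(qrB, rhs), error = function(e) NULL)
        if (is.null(xB) || anyNA(xB)) next
        x[B] <- xB
        consider(x)
      }
    }
  }
  if (is.null(best)) list(objective = NA_real_, x = NULL)
  else list(objective = best, x = bestX)
}

#' Generate a random toy network with a known optimum
#'
#' Builds a connected exchange-conversion-exchange network: an uptake
#' exchange for the first metabolite, a chain of conversions with random
#' positive integer coefficients through all metabolites, extra random
#' conversion reactions, and a secretion exchange for the last metabolite,
#' which is the (maximisation) objective. All bounds are finite, and the
#' optimum computed by [enumerateLPOptimum()] is stored as attributes.
#'
#' @param nMets number of internal metabolites (<= 6).
#' @param nRxns total number of reactions (<= 8, >= nMets + 1).
#' @param seed integer seed.
#' @return a \linkS4class{MetabolicModel} with attributes
#'   \code{"enumeratedOptimum"} (objective value) and
#'   \code{"objectiveReaction"}.
#' @export
genToyNetwork <- function(nMets = 3, nRxns = 6, seed = 1L) {
  stopifnot(nMets >= 2, nMets <= 6, nRxns <= 8, nRxns >= nMets + 3)
  set.seed(as.integer(seed))
  metIds <- paste0("m", seq_len(nMets))
  mets <- data.frame(id = c(metIds, paste0(metIds, "_ex")),
                     name = c(metIds, paste0(metIds, " (extracellular)")),
                     compartment = rep(c("c", "e"), each = nMets),
                     formula = NA_character_, charge = NA_real_,
                     stringsAsFactors = FALSE)
  rows <- list()
  st <- list()
  addr <- function(id, stoich, lower, upper) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = id, lower = lower, upper = upper, gpr = "",
      subsystem = "Other", stringsAsFactors = FALSE)
    st[[length(st) + 1L]] <<- stoich
  }
  cap <- 10
  # uptake exchange on m1 (via its extracellular twin + implicit transport
  # folded in: the exchange consumes m1_ex, a transport links m1_ex <-> m1)
  addr("EX_m1_ex", stats::setNames(-1, "m1_ex"), -cap, 0)
  addr("T_m1", stats::setNames(c(-1, 1), c("m1_ex", "m1")), 0, 2 * cap)
  # conversion chain m1 -> m2 -> ... -> mN
  for (i in seq_len(nMets - 1L)) {
    a <- sample(1:3, 1)
    b <- sample(1:3, 1)
    addr(paste0("R", i),
         stats::setNames(c(-a, b), c(metIds[i], metIds[i + 1L])),
         0, 2 * cap)
  }
  # extra random conversions
  nExtra <- nRxns - nMets - 3L
  for (k in seq_len(max(0L, nExtra))) {
    ij <- sample(nMets, 2)
    addr(paste0("X", k),
         stats::setNames(c(-sample(1:3, 1), sample(1:3, 1)),
                         metIds[ij]),
         if (stats::runif(1) < 0.3) -2 * cap else 0, 2 * cap)
  }
  addr("T_out", stats::setNames(c(-1, 1),
                                c(metIds[nMets], paste0(metIds[nMets], "_ex"))),
       0, 2 * cap)
  outEx <- paste0("EX_", metIds[nMets], "_ex")
  addr(outEx, stats::setNames(-1, paste0(metIds[nMets], "_ex")),
       0, 2 * cap)
  # ATPM/biomass designations are not meaningful for toy fixtures; reuse the
  # sink exchange so the container invariants hold
  rxn <- do.call(rbind, rows)
  m <- makeModel(paste0("toy", seed), "toy network", mets, rxn, st,
                 biomassReaction = outEx, atpmReaction = "T_out",
                 check = FALSE)
  obj <- as.numeric(rxn$id == outEx)
  opt <- enumerateLPOptimum(obj, m@S, rxn$lower, rxn$upper)
  attr(m, "enumeratedOptimum") <- opt$objective
  attr(m, "objectiveReaction") <- outEx
  m
}
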