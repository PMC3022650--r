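# Seeded generators: determinism, embedded structure, and the enumeration
# oracle.

test_that("generators are pure functions of their seed", {
  o1 <- genChemostatObs(pcarDefault, generatorConfig(seed = 5, noiseSd = 0.03))
  o2 <- genChemostatObs(pcarDefault, generatorConfig(seed = 5, noiseSd = 0.03))
  o3 <- genChemostatObs(pcarDefault, generatorConfig(seed = 6, noiseSd = 0.03))
  expect_identical(o1, o2)
  expect_false(identical(o1, o3))
  y1 <- genYieldRecords(pproDefault, c("btd_e", "lac_e"),
                        cfg = generatorConfig(seed = 5, noiseSd = 0.03))
  y2 <- genYieldRecords(pproDefault, c("btd_e", "lac_e"),
                        cfg = generatorConfig(seed = 5, noiseSd = 0.03))
  expect_identical(y1, y2)
  t1 <- genToyNetwork(3, 6, seed = 9)
  t2 <- genToyNetwork(3, 6, seed = 9)
  expect_identical(t1@S, t2@S)
  expect_identical(attr(t1, "enumeratedOptimum"),
                   attr(t2, "enumeratedOptimum"))
})

test_that("noiseless chemostat observations embed the linear ATP structure", {
  obs <- genChemostatObs(pcarDefault, generatorConfig(seed = 1))
  fit <- fitMaintenance(pcarDefault, obs)
  # doubling mu moves qATP by exactly GAM * delta-mu
  q <- fit@points$qatp
  mu <- fit@points$mu
  expect_equal(diff(q) / diff(mu), rep(97.5, 3), tolerance = 1e-6)
})

test_that("noiseless yield records round-trip the embedded nGAM", {
  yr <- genYieldRecords(pproDefault, c("btd_e", "actn_e"), mu = 0.144)
  expect_equal(as.numeric(estimateNgamFromYields(pproDefault, yr)), 2.80,
               tolerance = 1e-6)
  expect_identical(nrow(genYieldRecords(pproDefault, character(0))), 0L)
})

test_that("a unit-coefficient chain has the trivial optimum", {
  m <- chainModel(coefA = 1, coefB = 1, cap = 10)
  opt <- enumerateLPOptimum(as.numeric(reactions(m)$id == "EX_b_e"),
                            m@S, reactions(m)$lower, reactions(m)$upper)
  expect_equal(opt$objective, 10, tolerance = 1e-9)
})

test_that("generated toy fixtures validate and match their stored optimum", {
  for (s in c(3, 14, 27)) {
    tn <- genToyNetwork(4, 8, seed = s)
    expect_length(validateModel(tn), 0)
    cond <- makeCondition(attr(tn, "objectiveReaction"),
                          uptakeLimits = c(m1_ex = 10),
                          freeExchanges = character(0))
    sol <- solveFBA(tn, cond)
    expect_equal(objectiveValue(sol), attr(tn, "enumeratedOptimum"),
                 tolerance = 1e-7)
  }
})

test_that("noise is truncated and never flips flux signs", {
  for (s in 1:20) {
    obs <- genChemostatObs(pcarDefault,
                           generatorConfig(seed = s, noiseSd = 0.2))
    expect_true(all(obs$EX_actn_e < 0))
    expect_true(all(obs$EX_ac_e > 0))
  }
})
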