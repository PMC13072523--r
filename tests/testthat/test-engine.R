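test_that("TOY3 weighting reproduces the hand-computed cells and sums", {
  m <- toy3_model()
  a <- toy3_base_assessment()   # X1 = 2 (double), X2 = 1, X3 = -3
  w <- apply_weights(m, a, strategy = "row")
  expect_equal(unname(w$values),
               rbind(c(0, 8, 4), c(3, 0, 2), c(-6, -3, 0)))
  expect_equal(active_sums(w), c(X1 = 12, X2 = 5, X3 = -9))
  expect_equal(passive_sums(w), c(X1 = -3, X2 = 5, X3 = 6))
  expect_equal(active_sums(w, "X1"), 12)
  expect_equal(passive_sums(w, "X3"), 6)
  expect_error(active_sums(w, "X9"), "unknown entity")
  expect_equal(total_risk_score(w), 16)
})

test_that("unit weights without doubling recover the absolute matrix", {
  m <- toy3_model()
  ent <- m$entities
  ent$double <- FALSE
  m1 <- rimeda_model(m$perspectives, ent, m$matrix, id = "toy-flat")
  a <- rimeda_assessment(c(X1 = 1, X2 = 1, X3 = 1))
  w <- apply_weights(m1, a)
  expect_equal(unname(w$values), abs(unclass(unname(m$matrix))))
  expect_equal(active_sums(w), c(X1 = 3, X2 = 5, X3 = 3))
  expect_equal(passive_sums(w), c(X1 = 5, X2 = 3, X3 = 3))
})

test_that("zero weights annihilate rows (and columns under row_col)", {
  cfg <- generator_config(n_entities = 4, domain_palette = list(0:3),
                          seed = 11)
  m <- random_model(cfg)
  ids <- m$entities$id
  zero <- rimeda_assessment(setNames(rep(0L, 4), ids))
  for (strategy in c("row", "row_col")) {
    w <- apply_weights(m, zero, strategy)
    expect_true(all(w$values == 0))
    expect_equal(total_risk_score(w), 0)
  }
  one_zero <- rimeda_assessment(setNames(c(0L, 1L, 1L, 1L), ids))
  w <- apply_weights(m, one_zero, "row")
  expect_equal(active_sums(w)[[1]], 0)
  expect_true(all(w$values[1, ] == 0))
  w2 <- apply_weights(m, one_zero, "row_col")
  expect_true(all(w2$values[1, ] == 0) && all(w2$values[, 1] == 0))
})

test_that("Q-value conventions follow their definitions", {
  expect_equal(q_value(12, -3, "active_sign"), 36)
  expect_equal(q_value(-9, 6, "product"), -54)
  expect_equal(q_value(-9, 6, "active_sign"), -54)
  expect_equal(q_value(-9, -6, "active_sign"), -54)  # both negative stays reducing
  expect_equal(q_value(-9, -6, "product"), 54)
  expect_equal(q_value(0, 17), 0)
  expect_equal(q_value(c(1, -2), c(5, 5)), c(5, -10))
  expect_error(q_value(1, 1, "magic"), "should be one of")
})

test_that("factor classification matches mean-threshold hand comparison", {
  # TOY3 magnitudes: |AS| 12, 5, 9 (mean 8.67); |PS| 3, 5, 6 (mean 4.67)
  cls <- classify_factors(c(X1 = 12, X2 = 5, X3 = -9),
                          c(X1 = -3, X2 = 5, X3 = 6))
  expect_equal(cls, c(X1 = "active", X2 = "reactive", X3 = "critical"))
  # single dominant entity: dominant critical, rest inert
  cls <- classify_factors(c(a = 9, b = 0, c = 0), c(a = 7, b = 0, c = 0))
  expect_equal(cls, c(a = "critical", b = "inert", c = "inert"))
  # degenerate all-zero system: everything inert
  cls <- classify_factors(c(a = 0, b = 0), c(a = 0, b = 0))
  expect_equal(cls, c(a = "inert", b = "inert"))
  # ties resolve as ">=": |AS| equal to the mean counts as pronounced
  cls <- classify_factors(c(a = 2, b = 2), c(a = 1, b = 3))
  expect_equal(unname(cls), c("active", "critical"))
  # every category reachable in one constructed four-entity system
  cls <- classify_factors(c(a = 10, b = 1, c = 10, d = 1),
                          c(a = 1, b = 10, c = 10, d = 1))
  expect_setequal(unname(cls), c("active", "reactive", "critical", "inert"))
  # median scheme and fixed cut-offs are available
  expect_equal(unname(classify_factors(c(5, 1), c(1, 5), scheme = "median")),
               c("active", "reactive"))
  expect_equal(unname(classify_factors(c(5, 1), c(1, 5),
                                       scheme = list(active = 4, passive = 4))),
               c("active", "reactive"))
})

test_that("engine sums match the naive double-loop oracle on random models", {
  for (k in 1:60) {
    cfg <- generator_config(n_entities = 2 + (k %% 5), seed = 1000 + k,
                            negative_cell_prob = 0.3, double_prob = 0.3)
    m <- random_model(cfg)
    a <- random_assessment(m, seed = 2000 + k)
    strategy <- if (k %% 2 == 0) "row" else "row_col"
    w <- apply_weights(m, a, strategy)
    ref <- oracle_weighted(m, as.list(a$weights), strategy)
    expect_equal(unclass(w$values), ref)
    s <- oracle_sums(ref)
    expect_equal(active_sums(w), s$active)
    expect_equal(passive_sums(w), s$passive)
    expect_equal(total_risk_score(w), oracle_total(ref))
    # total score equals twice the cell sum under both strategies
    expect_equal(total_risk_score(w), 2 * sum(ref))
  }
})

test_that("the row-strategy score is linear with coefficients 2*delta*rowsum", {
  m <- toy3_model()
  base <- rimeda_assessment(c(X1 = 1, X2 = 1, X3 = 1))
  coef_expected <- c(X1 = 2 * 2 * 3, X2 = 2 * 1 * 5, X3 = 2 * 1 * 3)
  s0 <- total_risk_score(apply_weights(m, base, "row"))
  for (id in names(coef_expected)) {
    w <- base$weights; w[[id]] <- w[[id]] + 1L
    s1 <- total_risk_score(apply_weights(m, rimeda_assessment(w), "row"))
    expect_equal(s1 - s0, coef_expected[[id]])
  }
})

test_that("raising a nonnegative-domain weight never lowers the row score", {
  for (k in 1:20) {
    cfg <- generator_config(n_entities = 4, seed = 3000 + k,
                            domain_palette = list(0:3, 1:3))
    m <- random_model(cfg)
    a <- random_assessment(m, seed = 4000 + k)
    s0 <- total_risk_score(apply_weights(m, a, "row"))
    domains <- setNames(m$entities$weight_domain, m$entities$id)
    for (id in m$entities$id) {
      higher <- domains[[id]][domains[[id]] > a$weights[[id]]]
      if (length(higher) == 0) next
      w <- a$weights; w[[id]] <- higher[1]
      s1 <- total_risk_score(apply_weights(m, rimeda_assessment(w), "row"))
      expect_gte(s1, s0)
    }
  }
})

test_that("compute_risk orchestrates indices, score and band", {
  m <- toy3_model()
  r <- compute_risk(m, toy3_base_assessment())
  expect_s3_class(r, "rimeda_result")
  expect_equal(r$total_score, 16)
  expect_equal(r$indices$entity, c("X1", "X2", "X3"))
  expect_equal(r$indices$active_sum, c(12, 5, -9))
  expect_equal(r$indices$passive_sum, c(-3, 5, 6))
  expect_equal(r$indices$q_value, c(36, 25, -54))
  expect_equal(r$indices$category, c("active", "reactive", "critical"))
  expect_equal(unname(r$score_bounds), c(-8, 84))
  # invalid assessments are refused up front
  expect_error(compute_risk(m, rimeda_assessment(c(X1 = 1, X2 = 0, X3 = 1))),
               "invalid assessment")
})
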