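test_that("TOY3 analytic score bounds equal brute-force enumeration", {
  m <- toy3_model()
  scores <- oracle_all_scores(m)   # all 4 * 3 * 4 = 48 assessments
  expect_equal(length(scores), 48)
  b <- score_bounds(m)
  expect_equal(b$min, min(scores))
  expect_equal(b$max, max(scores))
  expect_equal(c(b$min, b$max), c(-8, 84))
  # the recorded assessments actually achieve the bounds
  expect_equal(total_risk_score(apply_weights(
    m, rimeda_assessment(b$assessment_min))), b$min)
  expect_equal(total_risk_score(apply_weights(
    m, rimeda_assessment(b$assessment_max))), b$max)
})

test_that("analytic and exhaustive bounds agree on random small models", {
  for (k in 1:25) {
    cfg <- generator_config(n_entities = 2 + (k %% 4), seed = 100 + k,
                            negative_cell_prob = 0.3, double_prob = 0.3)
    m <- random_model(cfg)
    scores <- oracle_all_scores(m)
    b <- score_bounds(m)
    expect_equal(b$min, min(scores), info = k)
    expect_equal(b$max, max(scores), info = k)
  }
})

test_that("row_col endpoint-corner bounds equal brute-force enumeration", {
  for (k in 1:15) {
    cfg <- generator_config(n_entities = 2 + (k %% 3), seed = 300 + k,
                            negative_cell_prob = 0.3, double_prob = 0.3)
    m <- random_model(cfg)
    m$weighting_strategy <- "row_col"
    scores <- oracle_all_scores(m, "row_col")
    b <- score_bounds(m)
    expect_equal(b$min, min(scores), info = k)
    expect_equal(b$max, max(scores), info = k)
  }
})

test_that("degenerate single-domain models have collapsed bounds", {
  ent <- entity_def("S1", "solo", "P", 0L)
  ent2 <- entity_def("S2", "solo2", "P", 0L)
  m <- rimeda_model(data.frame(id = "P", name = "p"),
                    rbind(ent, ent2),
                    influence_matrix(rbind(c(0, 3), c(2, 0)), c("S1", "S2")))
  b <- score_bounds(m)
  expect_equal(c(b$min, b$max), c(0, 0))
})

test_that("index ranges match exhaustive enumeration on TOY3", {
  m <- toy3_model()
  grid <- all_assessments(m)
  per <- lapply(seq_len(nrow(grid)), function(k) {
    w <- oracle_weighted(m, as.list(grid[k, , drop = FALSE]))
    s <- oracle_sums(w)
    data.frame(as_ = s$active, ps_ = s$passive,
               q = q_value(s$active, s$passive, m$q_convention))
  })
  per <- do.call(rbind, per)
  ir <- index_ranges(m)
  expect_equal(unname(ir$active), c(min(per$as_), max(per$as_)))
  expect_equal(unname(ir$passive), c(min(per$ps_), max(per$ps_)))
  expect_equal(unname(ir$q), c(min(per$q), max(per$q)))
})

test_that("index ranges match exhaustive enumeration on random models", {
  for (k in 1:15) {
    cfg <- generator_config(n_entities = 2 + (k %% 4), seed = 500 + k,
                            negative_cell_prob = 0.35, double_prob = 0.3)
    m <- random_model(cfg)
    if (k %% 3 == 0) m$weighting_strategy <- "row_col"
    grid <- all_assessments(m)
    vals <- lapply(seq_len(nrow(grid)), function(j) {
      w <- oracle_weighted(m, as.list(grid[j, , drop = FALSE]))
      s <- oracle_sums(w)
      list(a = s$active, p = s$passive,
           q = q_value(s$active, s$passive, m$q_convention))
    })
    a <- unlist(lapply(vals, `[[`, "a"))
    p <- unlist(lapply(vals, `[[`, "p"))
    q <- unlist(lapply(vals, `[[`, "q"))
    ir <- index_ranges(m)
    expect_equal(unname(ir$active), c(min(a), max(a)), info = k)
    expect_equal(unname(ir$passive), c(min(p), max(p)), info = k)
    expect_equal(unname(ir$q), c(min(q), max(q)), info = k)
  }
})

test_that("an all-zero matrix collapses every index range to zero", {
  ids <- c("Z1", "Z2", "Z3")
  ent <- do.call(rbind, lapply(ids, function(i) {
    entity_def(i, i, "P", 0:3)
  }))
  m <- rimeda_model(data.frame(id = "P", name = "p"), ent,
                    influence_matrix(matrix(0L, 3, 3), ids))
  ir <- index_ranges(m)
  expect_equal(unname(ir$active), c(0, 0))
  expect_equal(unname(ir$passive), c(0, 0))
  expect_equal(unname(ir$q), c(0, 0))
  expect_equal(unname(m$score_bounds), c(0, 0))
})

test_that("what_if recomputes deltas consistently with compute_risk", {
  m <- toy3_model()
  base <- toy3_base_assessment()
  wi <- what_if(m, base, c(X2 = 3))
  expect_equal(wi$delta, 2 * 5 * (3 - 1))   # 2 * rowsum * weight change
  expect_equal(wi$result$total_score, 36)
  # field-for-field consistency with a direct recomputation
  direct <- compute_risk(m, rimeda_assessment(c(X1 = 2, X2 = 3, X3 = -3),
                                              label = base$label))
  expect_equal(wi$result$indices, direct$indices)
  expect_equal(wi$result$total_score, direct$total_score)
  # no-op change
  expect_equal(what_if(m, base, c(X2 = 1))$delta, 0)
  # flipping the inhibitor-style entity from +3 to -3 lowers the score
  up <- rimeda_assessment(c(X1 = 2, X2 = 1, X3 = 3))
  wi2 <- what_if(m, up, c(X3 = -3))
  expect_equal(wi2$delta, 2 * 3 * (-3 - 3))
  expect_lt(wi2$delta, 0)
  # inadmissible and unknown changes are refused
  expect_error(what_if(m, base, c(X2 = 0)), "invalid assessment")
  expect_error(what_if(m, base, c(X9 = 1)), "unknown entity")
})

test_that("exhaustive sweeps enumerate every admissible assessment", {
  m <- toy3_model()
  sw <- sweep_assessments(m, mode = "exhaustive")
  expect_equal(sw$n_evaluated, 48)
  b <- score_bounds(m)
  expect_equal(sw$score_min, b$min)
  expect_equal(sw$score_max, b$max)
  expect_equal(sum(sw$histogram$counts), 48)
  expect_equal(sw$per_entity_leverage,
               c(X1 = 2 * 2 * 3 * 3, X2 = 2 * 5 * 2, X3 = 2 * 3 * 6))
})

test_that("exhaustive sweeps beyond the cap are refused with guidance", {
  m <- canonical_model()
  expect_error(sweep_assessments(m, mode = "exhaustive"),
               "monte_carlo")
  # the canonical admissible space is 4^7 * 3^6 combinations
  expect_equal(rimeda:::n_combinations(m), 4^7 * 3^6)
})

test_that("Monte-Carlo sweeps are seed-deterministic and bracketed", {
  m <- toy3_model()
  b <- score_bounds(m)
  s1 <- sweep_assessments(m, mode = "monte_carlo", n = 400, seed = 42)
  s2 <- sweep_assessments(m, mode = "monte_carlo", n = 400, seed = 42)
  expect_identical(s1, s2)
  s3 <- sweep_assessments(m, mode = "monte_carlo", n = 400, seed = 43)
  expect_false(identical(s1$histogram$counts, s3$histogram$counts))
  expect_gte(s1$score_min, b$min)
  expect_lte(s1$score_max, b$max)
  expect_equal(sum(s1$histogram$counts), 400)
  expect_error(sweep_assessments(m, mode = "monte_carlo", n = 0), "n >= 1")
  # sampling does not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(sweep_assessments(m, n = 10, seed = 1))
  expect_equal(runif(1), before)
})
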