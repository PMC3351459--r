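write_expr_fixture <- function(path, body,
                               header = "gene\ts1\ts2\ts3\ts4",
                               cond = "#condition: s1=glc s2=glc s3=ace s4=ace") {
  writeLines(c(cond, header, body), path)
  path
}

test_that("expression TSV parses with the condition map line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_fixture(path, c("gA\t32\t128\t4\t4", "gB\t10\t10\t10\t10"))
  m <- read_expression(path)
  expect_identical(rownames(m$values), c("gA", "gB"))
  expect_identical(unname(m$conditions), c("glc", "glc", "ace", "ace"))
  expect_equal(m$values["gA", ], c(s1 = 32, s2 = 128, s3 = 4, s4 = 4))
})

test_that("condition maps can come from a sidecar YAML or an argument", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_fixture(path, "gA\t1\t2\t3\t4", cond = "# plain comment")
  expect_error(read_expression(path), "condition")
  side <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("s1: glc", "s2: glc", "s3: ace", "s4: ace"), side)
  m <- read_expression(path, conditions_file = side)
  expect_identical(unname(m$conditions), c("glc", "glc", "ace", "ace"))
  m2 <- read_expression(path, conditions = c(s1 = "a", s2 = "a",
                                             s3 = "b", s4 = "b"))
  expect_identical(unname(m2$conditions), c("a", "a", "b", "b"))
})

test_that("malformed expression tables are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_fixture(path, c("gA\t1\t2\t3\t4", "gB\t1\t2\t3"))
  expect_error(read_expression(path), "line 4: expected 5 fields")
  write_expr_fixture(path, "gA\t1\t-2\t3\t4")
  expect_error(read_expression(path), "line 3: negative")
  write_expr_fixture(path, "gA\t1\tx\t3\t4")
  expect_error(read_expression(path), "line 3: non-numeric")
  write_expr_fixture(path, c("gA\t1\t2\t3\t4", "gA\t1\t2\t3\t4"))
  expect_error(read_expression(path), "duplicate gene")
})

test_that("expression round-trips through the TSV writer", {
  toy <- toy2()
  sim <- simulate_expression(toy, "glucose", sigma_log2 = 0.2, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$matrix, path)
  back <- read_expression(path)
  expect_identical(back$conditions, sim$matrix$conditions)
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-12)
})

test_that("condition means are geometric means of replicates", {
  vals <- rbind(gA = c(2^5, 2^7, 50, 50), gB = c(3, 3, 7, 7))
  colnames(vals) <- paste0("s", 1:4)
  m <- expression_matrix(vals, c("glc", "glc", "ace", "ace"))
  es <- condition_means(m)
  expect_equal(es$means["gA", "glc"], 2^6)      # log-average of 2^5, 2^7
  expect_equal(es$means["gB", "ace"], 7)        # identical replicates
  expect_equal(unname(es$max_profile), c(64, 7))

  # a single-sample condition passes through unchanged
  m1 <- expression_matrix(vals[, 1:3], c("glc", "glc", "ace"))
  es1 <- condition_means(m1)
  expect_equal(es1$means["gA", "ace"], 50)

  # matches a direct recomputation on simulated data
  toy <- toy2()
  sim <- simulate_expression(toy, "acetate", sigma_log2 = 0.3, seed = 9)
  es2 <- condition_means(sim$matrix)
  for (cc in unique(unname(sim$matrix$conditions))) {
    cols <- which(sim$matrix$conditions == cc)
    expect_equal(es2$means[, cc],
                 2^rowMeans(log2(sim$matrix$values[, cols, drop = FALSE])))
  }
})

test_that("zero values demand an explicit floor", {
  vals <- rbind(gA = c(0, 4))
  colnames(vals) <- c("s1", "s2")
  m <- expression_matrix(vals, c("a", "b"))
  expect_error(condition_means(m), "floor_value")
  es <- condition_means(m, floor_value = 1e-6)
  expect_equal(es$means["gA", "a"], 1e-6)
})

test_that("condition means are scale-equivariant", {
  set.seed(21)
  vals <- matrix(2^stats::runif(40, 0, 8), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
  m <- expression_matrix(vals, c("a", "a", "b", "b"))
  es <- condition_means(m)
  # scaling one gene everywhere scales its mean, leaves its ratio pattern
  vals2 <- vals; vals2["g03", ] <- vals2["g03", ] * 8
  es2 <- condition_means(expression_matrix(vals2, c("a", "a", "b", "b")))
  expect_equal(es2$means["g03", ], 8 * es$means["g03", ])
  expect_equal(es2$means["g03", ] / es2$max_profile["g03"],
               es$means["g03", ] / es$max_profile["g03"])
  # scaling only one condition's samples changes the ratios
  vals3 <- vals; vals3["g03", 1:2] <- vals3["g03", 1:2] * 8
  es3 <- condition_means(expression_matrix(vals3, c("a", "a", "b", "b")))
  expect_false(isTRUE(all.equal(
    es3$means["g03", ] / es3$max_profile["g03"],
    es$means["g03", ] / es$max_profile["g03"])))
})

test_that("reaction ratios follow the GPR aggregation rules", {
  toy <- toy2()
  # hand-built means: GLCT gene at 40% of its cross-condition max
  genes <- c("gGlcT", "gAcT", "gGly", "gPdh1", "gPdh2",
             "gTca1", "gTca2", "gTca3", "gIcl", "gPrec")
  means <- matrix(100, length(genes), 2,
                  dimnames = list(genes, c("glucose", "acetate")))
  means["gGlcT", ] <- c(40, 100)
  means["gPdh1", ] <- c(30, 80)   # OR: sums 30+100 vs 80+100
  means["gPdh2", ] <- c(100, 100)
  means["gTca1", ] <- c(30, 60)   # AND(30,20)=20 vs AND(60,100)=60
  means["gTca2", ] <- c(20, 100)
  means["gTca3", ] <- c(10, 40)   # OR with the AND: 30 vs 100
  es <- expression_set(means)
  r <- reaction_ratios(toy$model, es, "glucose")
  expect_equal(unname(r["GLCT"]), 0.4)
  expect_equal(unname(r["PDH"]), 130 / 180)
  expect_equal(unname(r["TCA"]), 30 / 100)
  expect_equal(unname(r["GLYC"]), 1)      # argmax condition
  expect_equal(unname(r["BIOMASS"]), 1)   # no GPR -> unconstrained
  # ratios in [0,1] and exactly 1 in each reaction's argmax condition
  r_ac <- reaction_ratios(toy$model, es, "acetate")
  expect_true(all(r >= 0 & r <= 1) && all(r_ac >= 0 & r_ac <= 1))
  expect_true(all(pmax(r, r_ac)[c("GLCT", "PDH", "TCA", "ACT", "SHUNT")] == 1))
  expect_error(reaction_ratios(toy$model, es, "ribose"), "ribose")
})

test_that("missing genes and zero denominators never constrain a reaction", {
  toy <- toy2()
  # most genes unmeasured
  means <- rbind(gGlcT = c(40, 100), gPdh1 = c(20, 80))
  colnames(means) <- c("glucose", "acetate")
  es <- expression_set(means)
  r <- reaction_ratios(toy$model, es, "glucose")
  expect_equal(unname(r["GLCT"]), 0.4)
  expect_equal(unname(r["PDH"]), 20 / 80)  # gPdh2 missing, dropped from sum
  expect_equal(unname(r["TCA"]), 1)        # wholly unmeasured
  # all-zero profile: denominator 0 -> unconstrained
  means0 <- rbind(means, gGly = c(0, 0))
  r0 <- reaction_ratios(toy$model, expression_set(means0), "glucose")
  expect_equal(unname(r0["GLYC"]), 1)
})

test_that("the significance filter scales only well-separated reactions", {
  toy <- toy2()
  sim <- simulate_expression(toy, "glucose", sigma_log2 = 0.1, fold = 8,
                             seed = 5)
  expr <- condition_means(sim$matrix)
  eligible <- significance_filter(toy$model, sim$matrix, expr, "glucose",
                                  alpha = 0.05)
  # strongly separated genes (delta = 6 log2 units, sigma = 0.1): eligible
  expect_true("ACT" %in% eligible)
  expect_true("SHUNT" %in% eligible)
  # reactions whose max is the challenge condition itself are never scaled
  expect_false("GLCT" %in% eligible)

  # identical replicate sets: p = 1, nothing eligible
  vals <- matrix(5, 4, 4, dimnames = list(c("gGlcT", "gAcT", "gAckA", "gIcl"),
                                          paste0("s", 1:4)))
  flat <- expression_matrix(vals, c("glucose", "glucose", "acetate", "acetate"))
  es_flat <- condition_means(flat)
  expect_length(significance_filter(toy$model, flat, es_flat, "glucose"), 0)

  # the filtered run scales no more reactions than the unfiltered run
  bl <- toy2_baseline()$baseline
  res_unf <- prioritize(toy$model, bl, expr, "glucose")
  res_fil <- prioritize(toy$model, bl, expr, "glucose", filter_alpha = 0.05,
                        matrix = sim$matrix)
  expect_lte(res_fil$n_scaled, res_unf$n_scaled)
  expect_gt(res_unf$n_scaled, 0)
})

test_that("the Welch test matches the analytic t statistic on separated data", {
  # replicates 4 log2 units apart with sd 0.1: p far below 0.05
  xa <- c(5.0, 5.1)
  xb <- c(9.0, 9.1)
  p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
  expect_lt(p, 0.05)
  # the same separation expressed through the filter
  vals <- 2^rbind(gIcl = c(xa, xb))
  colnames(vals) <- paste0("s", 1:4)
  m <- expression_matrix(vals, c("glucose", "glucose", "acetate", "acetate"))
  toy <- toy2()
  es <- condition_means(m)
  expect_identical(
    significance_filter(toy$model, m, es, "glucose", alpha = 0.05), "SHUNT")
})
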