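test_that("the stability score is the baseline-corrected summed difference", {
  expect_equal(stability_score(rep(0.3, 12), rep(0.3, 12)), 0)
  # uniform offset cancels through the baseline
  expect_equal(stability_score(rep(0.7, 12), rep(0, 12)), 0)
  # worked toy difference curve
  d <- c(0, 0, 0, 0, 0.5, 1, 1, 1, 0.5, 0, 0, 0)
  expect_equal(stability_score(d, rep(0, 12)), 4.0)
  # adding c only at the 8 temperatures above 44 degC shifts the score by 8c
  hot <- c(rep(0, 4), rep(1, 8))  # gradient positions 5..12 are > 44 degC
  expect_equal(stability_score(d + 0.3 * hot, rep(0, 12)),
               4.0 + 0.3 * 8, tolerance = 1e-12)
  # arbitrary curves: invariance to a constant added everywhere
  set.seed(1)
  h <- rnorm(12); m <- rnorm(12)
  expect_equal(stability_score(h + 1.7, m), stability_score(h, m),
               tolerance = 1e-12)
  # undefined without the first two anchor temperatures
  h2 <- h; h2[1] <- NA
  expect_true(is.na(stability_score(h2, m)))
})

test_that("fold changes are differences against the 37.0 degC channel", {
  temps <- c(37, 40, 44)
  set.seed(2)
  v <- matrix(rnorm(10 * 6, 18), 10, 6)
  tab <- make_table(v, condition = rep(c("mock", "heat"), each = 3),
                    replicate = 1, temperature_C = rep(temps, 2))
  cur <- fold_changes(tab)
  expect_true(all(cur$mock[, 1, 1] == 0))
  for (ti in 1:3)
    expect_equal(unname(cur$heat[, ti, 1]), unname(v[, 3 + ti] - v[, 4]))
  # intensity halving gives fc = -1
  vh <- cbind(rep(18, 3), rep(17, 3), rep(18, 3), rep(17, 3))
  tab2 <- make_table(vh, condition = rep(c("mock", "heat"), each = 2),
                     replicate = 1, temperature_C = rep(c(37, 44), 2))
  cur2 <- fold_changes(tab2)
  expect_true(all(cur2$heat[, 2, 1] == -1))
  expect_equal(unname(cur2$n_temps), rep(2, 3))
  tab3 <- make_table(vh[, -1], condition = c("mock", "heat", "heat"),
                     replicate = 1, temperature_C = c(44, 37, 44))
  expect_error(fold_changes(tab3), "37.0")
})

test_that("bootstrap is degenerate with one replicate and deterministic under seed", {
  set.seed(3)
  heat <- array(rnorm(20 * 12), dim = c(20, 12, 1),
                dimnames = list(sprintf("P%02d", 1:20), NULL, NULL))
  mock <- array(rnorm(20 * 12), dim = c(20, 12, 1),
                dimnames = dimnames(heat))
  curves <- structure(list(heat = heat, mock = mock,
                           temperatures = seq(37, 66, length.out = 12),
                           n_temps = setNames(rep(12, 20),
                                              dimnames(heat)[[1]])),
                      class = "tpp_curves")
  b <- bootstrap_scores(curves, n_rounds = 500, seed = 4)
  expect_equal(apply(b, 1, sd), setNames(rep(0, 20), rownames(b)))
  expect_equal(b[, 1],
               sapply(1:20, function(i)
                 stability_score(heat[i, , 1], mock[i, , 1])),
               ignore_attr = TRUE)
  heat2 <- array(rnorm(20 * 12 * 3), dim = c(20, 12, 3),
                 dimnames = dimnames(heat))
  curves2 <- structure(list(heat = heat2, mock = mock,
                            temperatures = curves$temperatures,
                            n_temps = curves$n_temps),
                       class = "tpp_curves")
  b1 <- bootstrap_scores(curves2, n_rounds = 100, seed = 5)
  b2 <- bootstrap_scores(curves2, n_rounds = 100, seed = 5)
  expect_identical(b1, b2)
})

test_that("bootstrap summaries converge to exhaustive enumeration", {
  # 3 temperatures, 2 heat x 2 mock replicates: 4^3 = 64 composite curves
  set.seed(6)
  nP <- 30
  heat <- array(rnorm(nP * 3 * 2, 0, 1), dim = c(nP, 3, 2),
                dimnames = list(sprintf("P%02d", 1:nP), NULL, NULL))
  mock <- array(rnorm(nP * 3 * 2, 0, 1), dim = c(nP, 3, 2),
                dimnames = dimnames(heat))
  curves <- structure(list(heat = heat, mock = mock,
                           temperatures = c(37, 37.8, 44),
                           n_temps = setNames(rep(3, nP),
                                              dimnames(heat)[[1]])),
                      class = "tpp_curves")
  grid <- expand.grid(h1 = 1:2, h2 = 1:2, h3 = 1:2,
                      m1 = 1:2, m2 = 1:2, m3 = 1:2)
  exact <- sapply(seq_len(nP), function(i) {
    sc <- apply(grid, 1, function(g) {
      hc <- c(heat[i, 1, g[1]], heat[i, 2, g[2]], heat[i, 3, g[3]])
      mc <- c(mock[i, 1, g[4]], mock[i, 2, g[5]], mock[i, 3, g[6]])
      d <- hc - mc
      sum(d - mean(d[1:2]))
    })
    c(mean = mean(sc), sd = sd(sc))
  })
  for (rounds in c(500, 5000)) {
    b <- bootstrap_scores(curves, n_rounds = rounds, seed = 7)
    mc_se <- exact["sd", ] / sqrt(rounds)
    dev <- abs(rowMeans(b) - exact["mean", ]) / mc_se
    expect_lt(mean(dev), 2)
    expect_gt(mean(abs(rowMeans(b) - exact["mean", ]) <= 2 * mc_se), 0.85)
  }
})

test_that("per-round standardization and the deviation test behave as built", {
  set.seed(8)
  boot <- matrix(rnorm(100 * 200), 100, 200,
                 dimnames = list(sprintf("P%03d", 1:100), NULL))
  res <- zscore_and_test(boot)
  # assertable post-condition: each round standardized across proteins
  z <- scale(boot)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(mean(res$final_score), 0, tolerance = 1e-12)
  expect_equal(sd(res$final_score), 1, tolerance = 1e-12)
  # a planted strong positive protein dominates
  boot2 <- boot
  boot2["P050", ] <- boot2["P050", ] + 15
  res2 <- zscore_and_test(boot2)
  expect_equal(res2$protein_id[which.max(res2$final_score)], "P050")
  expect_equal(res2$protein_id[which.min(res2$p_adj_local)], "P050")
})

test_that("the empirical-null global FDR is calibrated and monotone", {
  set.seed(9)
  scores <- rnorm(5000)
  q <- global_fdr(scores)
  expect_gt(attr(q, "sigma0"), 0.95)
  expect_lt(attr(q, "sigma0"), 1.05)
  expect_lt(mean(q < 0.01), 0.01)
  # monotone non-increasing in |score|
  ord <- order(abs(scores))
  expect_true(all(diff(as.numeric(q)[ord]) <= 1e-12))
  expect_equal(as.numeric(q)[which.min(abs(scores))], max(as.numeric(q)),
               tolerance = 1e-12)
  expect_error(global_fdr(rep(0.5, 100)), "degenerate")
})

test_that("hit calling requires both FDRs and six quantified temperatures", {
  res <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    p_adj_local = c(0.005, 0.005, 0.005, 0.5),
    global_fdr = c(0.005, 0.05, 0.005, 0.005),
    final_score = c(2, 2, -2, 2),
    stringsAsFactors = FALSE)
  nt <- setNames(c(12, 12, 12, 12), res$protein_id)
  expect_identical(call_hits(res, nt),
                   c("stabilized", "none", "destabilized", "none"))
  nt["a"] <- 5
  expect_identical(call_hits(res, nt)[1], "none")
})

test_that("planted stability shifts drive aggregators' scores up end to end", {
  tr <- generate_proteome(n_proteins = 600, aggregator_fraction = 0.1,
                          seed = 10)
  tt <- simulate_tpp2d(tr, seed = 11)
  fit <- tpp2d(tt, seed = 12)
  agg <- tr$class[match(fit$results$protein_id, tr$protein_id)] ==
    "aggregator"
  expect_lt(wilcox.test(fit$results$final_score[agg],
                        fit$results$final_score[!agg],
                        alternative = "greater")$p.value, 0.01)
  expect_output(print(fit), "tpp2d_fit")
})
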