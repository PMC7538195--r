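test_that("quality filter enforces the two-peptide / two-replicate rule", {
  set.seed(1)
  v <- matrix(2^rnorm(5 * 6, 20), 5, 6,
              dimnames = list(sprintf("P%03d", 1:5), NULL))
  ps <- matrix(2L, 5, 3, dimnames = list(rownames(v), NULL))
  ps[1, ] <- 1L              # one unique peptide everywhere -> removed
  ps[2, ] <- c(2L, 1L, 1L)   # only one qualifying replicate -> removed
  tab <- make_table(v, condition = rep(c("heat", "mock"), each = 3),
                    replicate = rep(1:3, 2), scale = "raw",
                    peptide_support = ps)
  out <- filter_quality(tab)
  expect_identical(rownames(out$values), sprintf("P%03d", 3:5))
  # a protein quantified in too few replicates of one condition is dropped
  v2 <- v
  v2[3, 1:2] <- NA  # heat replicates 1 and 2 missing
  tab2 <- make_table(v2, condition = rep(c("heat", "mock"), each = 3),
                     replicate = rep(1:3, 2), scale = "raw",
                     peptide_support = ps)
  expect_identical(rownames(filter_quality(tab2)$values),
                   sprintf("P%03d", 4:5))
  # empty table passes through
  empty <- make_table(v[0, , drop = FALSE],
                      condition = rep(c("heat", "mock"), each = 3),
                      scale = "raw", peptide_support = ps[0, , drop = FALSE])
  expect_equal(nrow(filter_quality(empty)$values), 0)
  expect_error(filter_quality(make_table(v, condition = "heat",
                                         scale = "raw")),
               "peptide_support")
})

test_that("batch correction removes additive offsets and matches the LS oracle", {
  set.seed(2)
  v <- matrix(rnorm(20 * 6, 20), 20, 6)
  batch <- rep(c("b1", "b2"), each = 3)
  tab <- make_table(v, condition = "heat", batch = batch)
  # single batch: unchanged
  tab1 <- make_table(v, condition = "heat", batch = "b1")
  expect_identical(correct_batches(tab1)$values, tab1$values)
  # constant +1 on batch 2: removed exactly, within-batch contrasts kept
  voff <- v
  voff[, 4:6] <- voff[, 4:6] + 1
  out <- correct_batches(make_table(voff, condition = "heat", batch = batch))
  base <- correct_batches(tab)
  # offset gone up to the preserved per-protein grand mean (+0.5 here)
  expect_equal(out$values, base$values + 0.5, tolerance = 1e-12)
  for (b in unique(batch))
    expect_equal(rowMeans(out$values[, batch == b]),
                 rowMeans(out$values), tolerance = 1e-12)
  # random 3-batch data equals a direct per-protein normal-equations fit
  v3 <- matrix(rnorm(30 * 9, 15), 30, 9)
  b3 <- rep(c("b1", "b2", "b3"), each = 3)
  got <- correct_batches(make_table(v3, condition = "heat", batch = b3))
  oracle <- t(apply(v3, 1, function(y) {
    fit <- lm(y ~ factor(b3))
    residuals(fit) + mean(y)
  }))
  dimnames(oracle) <- dimnames(got$values)
  expect_lt(max(abs(got$values - oracle)), 1e-9)
  # idempotence
  expect_equal(correct_batches(got)$values, got$values, tolerance = 1e-9)
})

test_that("batch correction agrees with limma's removeBatchEffect on balanced data", {
  set.seed(3)
  v <- matrix(rnorm(50 * 8, 18), 50, 8)
  batch <- rep(c("b1", "b2"), each = 4)
  got <- correct_batches(make_table(v, condition = "heat",
                                    batch = batch))$values
  ref <- limma::removeBatchEffect(v, batch = batch)
  # both equalize batch means; they may differ by a per-protein constant
  delta <- got - ref
  expect_lt(max(apply(delta, 1, function(x) diff(range(x)))), 1e-9)
})

test_that("vsn-style calibration matches quantiles and preserves ranks", {
  set.seed(4)
  base <- 2^rnorm(400, 16, 1.5)
  v <- cbind(ch1 = base, ch2 = base, ch3 = base)
  tab <- make_table(v, condition = "heat", scale = "raw")
  out <- normalize_vs(tab)
  co <- attr(out, "vs_coefficients")
  expect_true(all(abs(co$a) < 1e-8) && all(abs(co$b - 1) < 1e-8))
  expect_equal(out$values[, 1], out$values[, 2])
  # channel at exactly twice the reference is mapped back onto it
  v2 <- cbind(ch1 = base, ch2 = 2 * base)
  out2 <- normalize_vs(make_table(v2, condition = "heat", scale = "raw"),
                       reference = "ch1")
  q1 <- quantile(out2$values[, 1], seq(0.1, 0.9, 0.1))
  q2 <- quantile(out2$values[, 2], seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(q1 - q2)), 1e-6)
  # strict monotonicity => rank preservation within channel
  expect_identical(unname(rank(out2$values[, 2])), unname(rank(v2[, 2])))
  # glog2 approaches log2(2x) for large x
  x <- c(1e4, 1e5, 1e6)
  expect_lt(max(abs(glog2(x) - log2(2 * x))), 1e-6)
})

test_that("coefficient transfer freezes the light calibration", {
  set.seed(5)
  base <- 2^rnorm(300, 16, 1)
  light <- make_table(cbind(ch1 = base, ch2 = 1.3 * base + 50),
                      condition = "heat", scale = "raw")
  ln <- normalize_vs(light, reference = "ch1")
  # heavy table identical to light: identical output
  heavy_same <- make_table(cbind(ch1 = base, ch2 = 1.3 * base + 50),
                           condition = "heat", scale = "raw",
                           silac = "heavy")
  hn <- transfer_normalization(heavy_same, ln)
  expect_equal(hn$values, ln$values)
  # a 4-fold heavy shift survives as ~ +2 on the glog2 scale
  heavy_shift <- make_table(cbind(ch1 = 4 * base, ch2 = 4 * (1.3 * base + 50)),
                            condition = "heat", scale = "raw",
                            silac = "heavy")
  hs <- transfer_normalization(heavy_shift, ln)
  expect_lt(max(abs((hs$values - ln$values) - 2)), 0.01)
  # empty heavy table passes through
  empty <- make_table(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("ch1", "ch2"))),
                      condition = "heat", scale = "raw")
  expect_equal(nrow(transfer_normalization(empty, ln)$values), 0)
  # unknown channel errors
  other <- make_table(matrix(base, ncol = 1,
                             dimnames = list(NULL, "chX")),
                      condition = "nope", scale = "raw")
  expect_error(transfer_normalization(other, ln), "missing calibration")
})

test_that("imputation draws from the down-shifted channel distribution", {
  set.seed(6)
  v <- matrix(rnorm(12000, 20, 1), ncol = 1,
              dimnames = list(sprintf("P%05d", 1:12000), "ch1"))
  miss <- sample(12000, 10000)
  v_obs <- v
  v_obs[miss, 1] <- NA
  tab <- make_table(v_obs, condition = "heat")
  out <- impute_missing(tab, seed = 7)
  expect_identical(out$values[-miss, 1], v_obs[-miss, 1])
  mu <- mean(v_obs[, 1], na.rm = TRUE)
  s <- sd(v_obs[, 1], na.rm = TRUE)
  imp <- out$values[miss, 1]
  # Monte-Carlo check of Normal(mu - 1.8 s, (0.3 s)^2)
  expect_gt(mean(imp), mu - 1.8 * s - 0.1)
  expect_lt(mean(imp), mu - 1.8 * s + 0.1)
  expect_lt(abs(sd(imp) - 0.3 * s), 0.05)
  # determinism and the no-missing identity
  expect_identical(impute_missing(tab, seed = 7)$values, out$values)
  full <- make_table(v, condition = "heat")
  expect_identical(impute_missing(full, seed = 1)$values, v)
})

test_that("solubility is the replicate-matched heat - mock difference", {
  set.seed(8)
  v <- matrix(rnorm(10 * 6, 18), 10, 6)
  tab <- make_table(v, condition = rep(c("heat", "mock"), 3),
                    time_h = rep(c(0, 1, 5), each = 2), replicate = 1)
  prof <- compute_solubility(tab)
  expect_equal(prof$timepoints, c(0, 1, 5))
  for (ti in 1:3)
    expect_equal(unname(prof$s[, ti, 1]),
                 unname(v[, 2 * ti - 1] - v[, 2 * ti]))
  # heat exactly half of mock (log2 scale: -1)
  v2 <- cbind(h = rep(17, 5), m = rep(18, 5))
  tab2 <- make_table(v2, condition = c("heat", "mock"), time_h = 0)
  expect_true(all(compute_solubility(tab2)$s == -1))
  # unmatched structure errors and names the offender
  tab3 <- make_table(v[, 1:3], condition = c("heat", "mock", "heat"),
                     time_h = c(0, 0, 1), replicate = 1)
  expect_error(compute_solubility(tab3), "t=1")
})

test_that("total solubility and synthesis ratios follow their definitions", {
  v <- cbind(np = c(18, 16), sds = c(18, 18))
  np <- make_table(v[, 1, drop = FALSE], condition = "preshock", time_h = 0)
  sds <- make_table(v[, 2, drop = FALSE], condition = "preshock",
                    time_h = 0, lysis = "SDS")
  ts <- compute_total_solubility(np, sds)
  expect_equal(unname(ts[, "preshock"]), c(0, -2))
  # synthesis: doubling by 5 h -> ratio 1; constant -> 0
  hv <- matrix(c(10, 10, 11, 10), 2, 2,
               dimnames = list(c("dbl", "flat"), c("pre", "t5")))
  heavy <- make_table(hv, condition = c("preshock", "heat"),
                      time_h = c(0, 5), silac = "heavy")
  sr <- compute_synthesis_ratios(heavy)
  expect_equal(unname(sr[, "5", "heat"]), c(1, 0))
  rk <- rank_upregulated(sr)
  expect_equal(rk$protein_id[1], "dbl")
  no_pre <- make_table(hv, condition = c("heat", "heat"),
                       time_h = c(0, 5), silac = "heavy")
  expect_error(compute_synthesis_ratios(no_pre), "pre-shock")
})

test_that("light and heavy fractions yield matching solubility on mirrored data", {
  tr <- generate_proteome(n_proteins = 300, aggregator_fraction = 0.2,
                          induced_fraction = 0, seed = 21)
  tab <- simulate_solubility_course(tr, noise_sd = 0.05, channel_sd = 0,
                                    batch_sd = 0, censor_quantile = 0,
                                    stall_depth = 0, seed = 22)
  light <- subset_channels(tab, tab$channel_meta$silac == "light")
  heavy <- subset_channels(tab, tab$channel_meta$silac == "heavy")
  ln <- normalize_vs(light)
  hn <- transfer_normalization(heavy, ln)
  pl <- compute_solubility(ln)
  ph <- compute_solubility(hn, silac = "heavy")
  agg <- tr$class == "aggregator"
  expect_gt(cor(pl$mean_s[, "0"], ph$mean_s[, "0"]), 0.9)
  # agreement is tight for most proteins; the glog transform compresses the
  # lowest-intensity heavy signals, so only the bulk is compared
  expect_lt(median(abs(pl$mean_s[agg, "0"] - ph$mean_s[agg, "0"])), 0.1)
})
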