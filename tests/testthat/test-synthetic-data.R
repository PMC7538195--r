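test_that("generated proteome has the requested size, class split and determinism", {
  tr <- generate_proteome(n_proteins = 2000, aggregator_fraction = 0.063,
                          seed = 1)
  expect_equal(nrow(tr), 2000)
  expect_equal(sum(tr$class == "aggregator"), 126)  # round(2000 * 0.063)
  tr2 <- generate_proteome(n_proteins = 2000, aggregator_fraction = 0.063,
                           seed = 1)
  expect_identical(tr, tr2)
  expect_error(generate_proteome(n_proteins = 10, seed = 1), "n_proteins")
  expect_error(generate_proteome(n_proteins = 100, aggregator_fraction = 0.7,
                                 seed = 1), "aggregator_fraction")
  expect_error(generate_proteome(n_proteins = 100), "seed")
})

test_that("planted truth respects the class invariants", {
  tr <- generate_proteome(n_proteins = 500, seed = 3)
  agg <- tr$class == "aggregator"
  expect_true(all(tr$true_drop[agg] < log2(2 / 3)))
  expect_true(all(tr$true_drop[!agg] == 0))
  expect_true(all(tr$true_slope[!agg] == 0))
  expect_true(all(tr$plateau >= 0 & tr$plateau < 1))
  expect_true(all(tr$disorder_fraction >= 0 & tr$disorder_fraction <= 1))
  seqs <- attr(tr, "sequences")
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)))
  # insoluble flag is exactly the planted pre-stress ratio below -0.6
  expect_identical(tr$insoluble_subpop, tr$total_sol_pre < -0.6)
  # every complex has >= 5 distinct members
  cpx <- attr(tr, "complexes")
  expect_true(all(table(cpx$complex_id) >= 5))
})

test_that("planted rank correlations are recovered from the emitted truth table", {
  tr <- generate_proteome(n_proteins = 4000, seed = 7)
  agg <- tr[tr$class == "aggregator", ]
  rho_ds <- cor(agg$true_drop, agg$true_slope, method = "spearman")
  expect_gte(rho_ds, -0.47)
  expect_lte(rho_ds, -0.37)
  rho_dis <- cor(agg$disorder_fraction, agg$true_slope, method = "spearman")
  expect_lt(abs(rho_dis - 0.25), 0.05)
})

test_that("aggregator sequences carry the planted composition and feature shifts", {
  tr <- generate_proteome(n_proteins = 2000, seed = 5)
  seqs <- attr(tr, "sequences")
  agg <- tr$class == "aggregator"
  comp <- aa_composition(seqs, tr$class)
  d <- comp$difference
  expect_true(all(d[c("K", "R", "E")] > 0))
  expect_true(all(d[c("I", "L", "V", "F")] < 0))
  # downstream class separations: more hydrophilic, heavier, more disordered
  gr <- gravy_score(seqs)
  expect_lt(wilcox.test(gr[agg], gr[!agg], alternative = "less")$p.value,
            0.01)
  expect_lt(wilcox.test(tr$mw[agg], tr$mw[!agg],
                        alternative = "greater")$p.value, 0.01)
  expect_lt(wilcox.test(tr$disorder_fraction[agg],
                        tr$disorder_fraction[!agg],
                        alternative = "greater")$p.value, 0.01)
})

test_that("melting_fraction is the plateau-lifted falling sigmoid", {
  expect_equal(melting_fraction(50, Tm = 50, melt_slope = 1, plateau = 0.1),
               0.55)
  expect_equal(melting_fraction(50, 50, 2, 0.3), (1 + 0.3) / 2)
  expect_equal(melting_fraction(-1e6, 50, 1, 0.1), 1)
  expect_equal(melting_fraction(1e6, 50, 1, 0.1), 0.1)
  Tgrid <- seq(30, 70, by = 0.5)
  f <- melting_fraction(Tgrid, 50, 1.5, 0.05)
  expect_true(all(diff(f) < 0))
  expect_error(melting_fraction(50, 50, 0, 0.1), "melt_slope")
  expect_error(melting_fraction(50, 50, 1, 1), "plateau")
})

test_that("noise-free recovery course reproduces the planted trajectories", {
  tr <- generate_proteome(n_proteins = 60, aggregator_fraction = 0.1,
                          seed = 2)
  # pin one aggregator to the worked relaxation example
  i <- which(tr$class == "aggregator")[1]
  tr$true_drop[i] <- -1
  tr$true_slope[i] <- 0.2
  tab <- simulate_solubility_course(tr, noise_sd = 0, channel_sd = 0,
                                    batch_sd = 0, censor_quantile = 0,
                                    seed = 4)
  v <- log2(tab$values)
  meta <- tab$channel_meta
  ratio <- function(p, t, r = 1) {
    h <- meta$channel_id[meta$condition == "heat" & meta$time_h == t &
                           meta$silac == "light" & meta$lysis == "NP40" &
                           meta$replicate == r]
    m <- sub("heat", "mock", h)
    v[p, h] - v[p, m]
  }
  sol <- which(tr$class == "soluble")[1]
  for (t in c(0, 1, 2, 3, 5)) expect_equal(ratio(sol, t), 0)
  expect_equal(sapply(c(0, 1, 2, 3, 5), ratio, p = i),
               c(-1.0, -0.8, -0.6, -0.4, 0.0))
  # conservation: total (SDS) expectation >= soluble (NP-40) expectation
  for (cond in c("heat", "mock", "preshock")) {
    sds <- meta$channel_id[meta$lysis == "SDS" & meta$condition == cond &
                             meta$replicate == 1]
    np <- meta$channel_id[meta$lysis == "NP40" & meta$condition == cond &
                            meta$time_h == 0 & meta$replicate == 1]
    expect_true(all(tab$values[, sds] >= tab$values[, np] - 1e-9))
  }
})

test_that("left-censoring at the 5% detection quantile leaves at most 7% missing", {
  tr <- generate_proteome(n_proteins = 1000, seed = 6)
  tab <- simulate_solubility_course(tr, censor_quantile = 0.05, seed = 8)
  expect_lte(mean(is.na(tab$values)), 0.07)
  # and the generator is deterministic
  tab2 <- simulate_solubility_course(tr, censor_quantile = 0.05, seed = 8)
  expect_identical(tab$values, tab2$values)
})

test_that("noise-free TPP curves reflect the planted stability shifts", {
  tr <- generate_proteome(n_proteins = 60, aggregator_fraction = 0.1,
                          seed = 9)
  tr$true_drop[] <- 0
  tr$delta_Tm[] <- 0
  tt <- simulate_tpp2d(tr, noise_sd = 0, channel_sd = 0, batch_sd = 0,
                       seed = 10)
  meta <- tt$channel_meta
  h1 <- meta$channel_id[meta$condition == "heat" & meta$replicate == 1]
  m1 <- meta$channel_id[meta$condition == "mock" & meta$replicate == 1]
  expect_equal(unname(tt$values[, h1]), unname(tt$values[, m1]))
  # +3 degC shift: heat soluble fraction >= mock at every T above 37.8
  tr$delta_Tm[] <- 3
  tt3 <- simulate_tpp2d(tr, noise_sd = 0, channel_sd = 0, batch_sd = 0,
                        seed = 10)
  hot <- meta$temperature_C[match(h1, meta$channel_id)] > 37.8
  expect_true(all(tt3$values[, h1][, hot] >= tt3$values[, m1][, hot]))
  near_tm <- which.min(abs(meta$temperature_C[match(h1, meta$channel_id)] -
                             median(tr$Tm)))
  expect_true(all(tt3$values[, h1][, near_tm] >
                    tt3$values[, m1][, near_tm]))
  tt3b <- simulate_tpp2d(tr, noise_sd = 0, channel_sd = 0, batch_sd = 0,
                         seed = 10)
  expect_identical(tt3$values, tt3b$values)
})

test_that("a simulated study round-trips through the TSV/FASTA writers", {
  tr <- generate_proteome(n_proteins = 60, seed = 12)
  tab <- simulate_solubility_course(tr, seed = 13)
  dir <- withr::local_tempdir()
  write_simulation(tr, list(course = tab), dir)
  back <- read_intensity_table(file.path(dir, "course_intensities.tsv"),
                               file.path(dir, "course_channels.tsv"))
  expect_equal(back$values, tab$values, tolerance = 1e-8)
  cpx <- read_complex_db(file.path(dir, "complexes.tsv"))
  expect_setequal(unique(cpx$complex_id),
                  unique(attr(tr, "complexes")$complex_id))
  feats <- sequence_features(file.path(dir, "sequences.fasta"))
  expect_equal(feats$protein_id, tr$protein_id)
})
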