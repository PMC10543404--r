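test_that("lambda_from_negatives implements the Poisson correction", {
  expect_equal(lambda_from_negatives(20000, 20000)$lambda, 0)
  expect_equal(lambda_from_negatives(7358, 20000)$lambda,
               -log(7358 / 20000))
  expect_equal(lambda_from_negatives(7358, 20000)$lambda, 0.99997,
               tolerance = 1e-4)

  sat <- lambda_from_negatives(0, 20000)
  expect_true(sat$saturated)
  expect_true(is.na(sat$lambda))
  expect_gt(sat$ci[1], 0)  # only a lower bound

  expect_error(lambda_from_negatives(21000, 20000))

  # monotone decreasing in n_neg
  lams <- vapply(c(5000, 10000, 15000, 19999),
                 function(k) lambda_from_negatives(k, 20000)$lambda,
                 numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("clopper-pearson lambda interval has ~95% coverage", {
  lam_true <- 0.15
  n <- 20480L
  set.seed(61)
  n_neg <- rbinom(1000, n, exp(-lam_true))
  cover <- vapply(n_neg, function(k) {
    ci <- lambda_from_negatives(k, n)$ci
    ci[1] <= lam_true && lam_true <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("concentration applies the chip volume scaling", {
  chip <- chip_spec()
  expect_equal(concentration(0, chip)$conc, 0)
  expect_equal(concentration(0.148, chip)$conc, 0.148 * 20480 / 9,
               tolerance = 1e-12)
  expect_equal(concentration(0.148, chip)$conc, 336.8, tolerance = 1e-3)
  # doubling the analyzed fraction halves copies/uL at fixed lambda
  half <- chip_spec(analyzed_fraction = 0.5)
  expect_equal(concentration(0.148, half)$conc,
               2 * concentration(0.148, chip)$conc)
  # linear in n_partitions, inverse in reaction volume
  expect_equal(concentration(0.148, chip_spec(n_partitions = 40960))$conc,
               2 * concentration(0.148, chip)$conc)
  expect_equal(concentration(0.148, chip_spec(reaction_volume = 18))$conc,
               concentration(0.148, chip)$conc / 2)
})

test_that("no editing gives zero drop-off within noise", {
  sim <- sim_editing_chip(fraction = 0, seed = 62)
  row <- quant_tamra(sim)
  expect_lt(row$fraction, 0.01)
  expect_lte(row$fraction_lo, row$fraction)
})

test_that("a 10% edit is recovered as ~10% fraction and ~34 copies/uL", {
  # single chip at the standard load: lambda_ref ~0.148, lambda_probe
  # ~0.133, so f ~0.10 and C_mut ~33.7 copies/uL
  rows <- lapply(1:4, function(b)
    quant_tamra(sim_editing_chip(fraction = 0.10, seed = 62 + b)))
  f <- mean(vapply(rows, `[[`, numeric(1), "fraction"))
  cm <- mean(vapply(rows, `[[`, numeric(1), "conc_mut"))
  expect_equal(f, 0.10, tolerance = 0.1)
  expect_equal(cm, 33.7, tolerance = 0.12)
})

test_that("difference and joint estimators agree across template loads", {
  # rain-free noise isolates the estimator comparison from gating
  # artifacts (the joint pattern estimator is sensitive to partitions
  # misgated by intermediate "rain" fluorescence; the per-channel
  # difference estimator largely cancels them)
  for (lam_ref in c(0.05, 0.15, 0.5, 1.5)) {
    conc <- lam_ref / std_chip$partition_volume
    sim <- sim_editing_chip(fraction = 0.10, conc = conc,
                            seed = round(100 * lam_ref) + 7,
                            noise = noise_model(rain_fraction = 0))
    gr <- gate_chip(sim)
    qd <- dropoff_quantify(gr, std_panel, std_chip, method = "difference",
                           n_boot = 300, seed = 1)
    qj <- dropoff_quantify(gr, std_panel, std_chip, method = "joint",
                           n_boot = 300, seed = 1)
    fd <- qd$dropoff[qd$dropoff$dye == "TAMRA", ]
    fj <- qj$dropoff[qj$dropoff$dye == "TAMRA", ]
    # joint point estimate inside the difference bootstrap interval
    expect_gte(fj$fraction, fd$fraction_lo)
    expect_lte(fj$fraction, fd$fraction_hi)
  }
})

test_that("the joint estimator corrects the naive ratio's bias at high load", {
  # At lambda_ref = 1.5 co-encapsulation is common: the naive
  # "(ref+, probe-) / ref+" ratio underestimates the mutant fraction
  # because partitions holding both a mutant and an intact template
  # light every probe. The corrected estimators do not share this bias.
  lam_ref <- 1.5
  conc <- lam_ref / std_chip$partition_volume
  f_true <- 0.10
  naive <- joint <- numeric(6)
  for (b in seq_len(6)) {
    sim <- sim_editing_chip(fraction = f_true, conc = conc, seed = 70 + b)
    gr <- gate_chip(sim)
    pc <- pattern_counts(gr, std_panel)
    marg <- pc$dropoff_marginals
    naive[b] <- marg$n_ref_pos_probe_neg[marg$dye == "TAMRA"] /
      marg$n_ref_pos[1]
    q <- dropoff_quantify(pc, std_panel, std_chip, method = "joint",
                          n_boot = 50, seed = b)
    joint[b] <- q$dropoff$fraction[q$dropoff$dye == "TAMRA"]
  }
  # naive estimator is badly biased downward; joint estimator is not
  expect_lt(mean(naive), 0.75 * f_true)
  expect_equal(mean(joint), f_true, tolerance = 0.1)
})

test_that("estimator is consistent across fractions and loads", {
  for (lam_ref in c(0.05, 0.15, 1.5)) {
    conc <- lam_ref / std_chip$partition_volume
    for (f_true in c(0.01, 0.1, 0.5)) {
      fs <- vapply(1:3, function(b) {
        sim <- sim_editing_chip(fraction = f_true, conc = conc,
                                seed = round(1000 * lam_ref) + 10 * b +
                                  round(100 * f_true))
        quant_tamra(sim, n_boot = 50, seed = b)$fraction
      }, numeric(1))
      mc_err <- 3 * stats::sd(fs) / sqrt(3) + 0.02 * f_true + 2e-3
      expect_lt(abs(mean(fs) - f_true), max(mc_err, 0.15 * f_true))
    }
  }
})

test_that("negative difference estimates are floored and flagged", {
  # a truly unedited chip lights both channels from the same templates,
  # so the channel difference is exactly zero
  row0 <- quant_tamra(sim_editing_chip(fraction = 0, seed = 80),
                      n_boot = 50)
  expect_equal(row0$lambda_mut, 0)
  expect_false(row0$floored)

  # with perfect calls the reference-negative set is a subset of the
  # probe-negative set, so negative differences arise only from gating
  # noise; rain provides exactly that channel-independent jitter
  rows <- lapply(1:8, function(b)
    quant_tamra(sim_editing_chip(fraction = 0, seed = 80 + b,
                                 noise = noise_model(rain_fraction = 0.01)),
                n_boot = 50))
  expect_true(any(vapply(rows, `[[`, logical(1), "floored")))
  expect_true(all(vapply(rows, `[[`, numeric(1), "fraction") >= 0))
})

test_that("saturated reference channel refuses quantification", {
  # enormous load: every partition positive on every channel
  sim <- sim_editing_chip(fraction = 0.1, conc = 1e5, seed = 90,
                          noise = noise_model(rain_fraction = 0))
  thr <- c(FAM = 3000, TAMRA = 3000, Cy5 = 3000, HEX = 3000)
  gr <- gate(sim$table, thr)
  expect_true(all(gr$counts$n_neg == 0))
  expect_error(dropoff_quantify(gr, std_panel, std_chip), "saturated")
})

test_that("euploid chips give ratio ~1 and cnv chips ratio ~0.5", {
  # calls rest on 95% bootstrap intervals, so any single simulated chip
  # has a ~5% chance of a CI missing the true ratio; assert calibrated
  # behavior over replicate chips instead of one draw
  sp_cnv <- make_cnv_species(std_panel, std_conc)
  calls_e <- calls_c <- character(8)
  r_e <- r_c <- numeric(8)
  for (b in 1:8) {
    sim_e <- sim_editing_chip(fraction = 0, seed = 900 + b)
    q_e <- dropoff_quantify(gate_chip(sim_e), std_panel, std_chip,
                            n_boot = 100, seed = b)
    cv_e <- cnv_ratio(q_e, n_boot = 500, seed = b)
    calls_e[b] <- cv_e$call
    r_e[b] <- cv_e$ratios$ratio[cv_e$ratios$dye == "TAMRA"]

    sim_c <- simulate_chip(std_panel, std_chip, sp_cnv, seed = 950 + b)
    q_c <- dropoff_quantify(gate_chip(sim_c), std_panel, std_chip,
                            n_boot = 100, seed = b)
    cv_c <- cnv_ratio(q_c, n_boot = 500, seed = b)
    calls_c[b] <- cv_c$call
    r_c[b] <- cv_c$ratios$ratio[cv_c$ratios$dye == "TAMRA"]
    if (b == 1)  # union-based total concentration ~ total template load
      expect_equal(cv_c$total_conc_union, std_conc, tolerance = 0.05)
  }
  expect_equal(mean(r_e), 1, tolerance = 0.05)
  expect_gte(mean(calls_e == "euploid"), 0.75)
  expect_false(any(calls_e == "hemizygous-reference"))
  expect_equal(mean(r_c), 0.5, tolerance = 0.05)
  expect_gte(mean(calls_c == "hemizygous-reference"), 0.75)
  expect_false(any(calls_c == "euploid"))
})

test_that("cnv bootstrap interval covers the true ratio at ~95%", {
  sp <- make_cnv_species(std_panel, std_conc)
  cover <- vapply(1:200, function(b) {
    sim <- simulate_chip(std_panel, std_chip, sp, seed = 1000 + b)
    q <- dropoff_quantify(gate_chip(sim), std_panel, std_chip,
                          n_boot = 50, seed = b)
    cv <- cnv_ratio(q, n_boot = 400, seed = b)
    r <- cv$ratios[cv$ratios$dye == "TAMRA", ]
    r$ratio_lo <= 0.5 && 0.5 <= r$ratio_hi
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("pooled pattern counts quantify few-event baselines", {
  # baseline at f = 1e-3: a single chip sees only ~3 mutant templates,
  # pooling 20 chips stabilizes the estimate
  f_true <- 1e-3
  sp <- make_editing_species(std_panel, std_conc, f_true, "TAMRA")
  pcs <- lapply(1:20, function(b) {
    sim <- simulate_chip(std_panel, std_chip, sp, seed = 2000 + b)
    pattern_counts(gate_chip(sim), std_panel)
  })
  pooled <- pool_pattern_counts(pcs)
  expect_equal(pooled$n_total, 20L * std_chip$n_partitions)
  q <- dropoff_quantify(pooled, std_panel, std_chip, n_boot = 200,
                        seed = 5)
  f_hat <- q$dropoff$fraction[q$dropoff$dye == "TAMRA"]
  expect_equal(f_hat, f_true, tolerance = 0.5)
})

test_that("replicate aggregation reports mean and sem", {
  qs <- lapply(1:3, function(b) {
    sim <- sim_editing_chip(fraction = 0.10, seed = 300 + b)
    dropoff_quantify(gate_chip(sim), std_panel, std_chip, n_boot = 50,
                     seed = b)
  })
  agg <- aggregate_quant(qs)
  expect_equal(nrow(agg), 3L)  # three drop-off probes
  tam <- agg[agg$probe == "CRLF2_TAMRA", ]
  expect_equal(tam$mean_fraction, 0.10, tolerance = 0.15)
  expect_true(is.finite(tam$sem_fraction))
})
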