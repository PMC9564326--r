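test_that("binding assembly is the plain identity dG = dG_MM/GBSA - TdS", {
  est <- entropy_estimate(minus_TdS_rtv = c(20, 22),
                          minus_TdS_conf = c(1.5, 1.1))
  rep <- assemble_binding(-27.5, est, label = "toy")
  expect_s3_class(rep, "binding_report")
  expect_equal(rep$dG_binding, -27.5 + est$total, tolerance = 1e-12)
  expect_equal(rep$minus_TdS, est$total)
  expect_true(is.na(rep$dG_binding_sd))  # no dG_sd supplied
  # quadrature when both SDs exist
  rep2 <- assemble_binding(-27.5, est, dG_sd = 0.8)
  expect_equal(rep2$dG_binding_sd, sqrt(0.8^2 + est$sd^2),
               tolerance = 1e-12)
  expect_error(assemble_binding(NaN, est), "non-finite")
})

test_that("assemble_binding accepts energy_components directly", {
  tc <- gen_toy_complex("stable", n_frames = 20, seed = 1)
  mm <- mmgbsa_interaction(list(tc$trajectory,
                                gen_toy_complex("stable", n_frames = 20,
                                                seed = 2,
                                                run_id = 2)$trajectory),
                           tc$params, n_snapshots = 5)
  rep <- assemble_binding(mm, entropy_estimate(3, 1))
  expect_equal(rep$dG_mmgbsa, unname(mm$mean["total"]))
  expect_equal(rep$dG_mmgbsa_sd, mm$sd)
  expect_equal(rep$dG_binding, unname(mm$mean["total"]) + 4)
})

test_that("percent contributions round to integers and sum near 100", {
  tab <- data.frame(group = c("A", "B", "C"),
                    energy = c(-13.0, -16.0, -3.0))
  out <- percent_contributions(tab, total = -25.0)
  expect_equal(out$percent, c("52%", "64%", "12%"))
  tab2 <- data.frame(group = c("A", "B"), energy = c(-6, -4))
  out2 <- percent_contributions(tab2)
  pc <- as.numeric(sub("%", "", out2$percent))
  expect_lte(abs(sum(pc) - 100), 2)
})

test_that("sub-percent contributions are rendered as <1%", {
  tab <- data.frame(group = c("big", "tiny", "tinyneg"),
                    energy = c(-99.5, -0.3, 0.2))
  out <- percent_contributions(tab, total = -100)
  expect_equal(out$percent[2], "<1%")
  expect_equal(out$percent[3], "<1%")
  expect_error(percent_contributions(tab, total = 0), "zero total")
})

test_that("mean_over_runs reproduces the worked three-run average", {
  m <- mean_over_runs(c(0.4, 5.0, -7.6))
  expect_equal(m$mean, -0.7333333, tolerance = 1e-6)
  expect_equal(.round1(m$mean), -0.7)
  expect_equal(m$n, 3)
  expect_equal(m$sd, sd(c(0.4, 5.0, -7.6)))
  expect_true(is.na(mean_over_runs(2.5)$sd))
  expect_error(mean_over_runs(numeric()), "no values")
})

test_that("half-away-from-zero rounding differs from banker's rounding", {
  expect_equal(.round1(0.25), 0.3)
  expect_equal(.round1(-0.25), -0.3)
  expect_equal(.round1(2.649999), 2.6)
  expect_identical(round(0.25, 1), 0.2)  # the convention we avoid
})

test_that("pooled t comparison reproduces a hand-checked P value", {
  cmp <- compare_complexes(list(mean = -24.8, sd = 1.0, n = 3),
                           list(mean = -25.4, sd = 0.7, n = 3),
                           labels = c("sulfo", "parent"))
  expect_equal(cmp$ddG, 0.6, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  sp <- sqrt(((3 - 1) * 1 + (3 - 1) * 0.49) / 4)
  t_ref <- 0.6 / (sp * sqrt(2 / 3))
  expect_equal(cmp$t, t_ref, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_ref), 4), tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 4), 0.4425)
})

test_that("comparison matches stats::t.test on raw vectors", {
  a <- c(-24.1, -25.6, -24.7)
  b <- c(-25.9, -25.0, -25.3)
  cmp <- compare_complexes(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-12)
  w <- compare_complexes(a, b, var_equal = FALSE)
  tw <- t.test(a, b)
  expect_equal(w$p_value, tw$p.value, tolerance = 1e-12)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-10)
})

test_that("comparison is antisymmetric in ddG and symmetric in P", {
  a <- c(1.2, 0.8, 1.5, 0.9)
  b <- c(2.0, 2.4, 1.8)
  ab <- compare_complexes(a, b)
  ba <- compare_complexes(b, a)
  expect_equal(ab$ddG, -ba$ddG)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("comparison rejects under-replicated inputs", {
  expect_error(compare_complexes(1, c(1, 2)), "insufficient replicates")
  expect_error(compare_complexes(list(mean = 1, sd = 0.1, n = 1),
                                 list(mean = 2, sd = 0.1, n = 3)),
               "insufficient replicates")
  expect_error(compare_complexes(list(mean = 1, sd = 0.1),
                                 c(1, 2)), "mean, sd and n")
})

test_that("identical samples give P = 1, not NaN", {
  cmp <- compare_complexes(c(2, 2, 2), c(2, 2, 2))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$t, 0)
})

test_that("print methods render the headline numbers", {
  est <- entropy_estimate(20, 1.5)
  rep <- assemble_binding(-27.5, est, label = "toy")
  txt <- capture.output(print(rep))
  expect_match(txt, "dG_binding", all = FALSE)
  expect_match(txt, "-6.0", all = FALSE, fixed = TRUE)
  cmp <- compare_complexes(list(mean = -24.8, sd = 1.0, n = 3),
                           list(mean = -25.4, sd = 0.7, n = 3))
  txt2 <- capture.output(print(cmp))
  expect_match(txt2, "P = 0.4425", all = FALSE, fixed = TRUE)
})
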