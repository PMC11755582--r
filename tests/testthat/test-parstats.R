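test_that("PAR closed form, degenerate cases and Table-2-style inputs", {
  expect_equal(compute_par(1, 1, 1, 1, 1, 1), 0)
  expect_equal(compute_par(TrA_R = 1, OI_R = 1, OE_R = 1,
                           TrA_C = 2, OI_C = 1, OE_C = 1),
               1 / 2 - 1 / 3, tolerance = 1e-12)
  # hand arithmetic: 5.44/21.41 - 4.61/19.17 = 0.0136070...
  expect_equal(compute_par(TrA_R = 4.61, OI_R = 9.34, OE_R = 5.22,
                           TrA_C = 5.44, OI_C = 10.57, OE_C = 5.40),
               0.0136, tolerance = 0.0001 / 0.0136)
  expect_error(compute_par(0, 1, 1, 1, 1, 1), "> 0")
  expect_error(compute_par(-1, 1, 1, 1, 1, 1), "> 0")
})

test_that("PAR is scale invariant and monotone in the expected directions", {
  set.seed(101)
  grid <- expand.grid(TrA = c(3, 4.6, 6), OI = c(7, 9.3, 12),
                      OE = c(4, 5.2, 7))
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    p0 <- compute_par(r$TrA, r$OI, r$OE, r$TrA * 1.2, r$OI * 1.2,
                      r$OE * 1.2)
    expect_equal(p0, 0, tolerance = 1e-12)  # proportional thickening
    p1 <- compute_par(r$TrA, r$OI, r$OE, r$TrA, r$OI, r$OE)
    for (c_scale in c(0.5, 2, 13)) {
      expect_equal(compute_par(c_scale * r$TrA, c_scale * r$OI,
                               c_scale * r$OE, c_scale * r$TrA,
                               c_scale * r$OI, c_scale * r$OE),
                   p1, tolerance = 1e-12)
    }
    base <- compute_par(r$TrA, r$OI, r$OE, r$TrA + 0.5, r$OI, r$OE)
    more <- compute_par(r$TrA, r$OI, r$OE, r$TrA + 1.0, r$OI, r$OE)
    expect_gt(more, base)  # TrA_C strictly increases PAR
    oi_up <- compute_par(r$TrA, r$OI, r$OE, r$TrA + 0.5, r$OI + 1, r$OE)
    oe_up <- compute_par(r$TrA, r$OI, r$OE, r$TrA + 0.5, r$OI, r$OE + 1)
    expect_lt(oi_up, base)  # OI_C / OE_C strictly decrease PAR
    expect_lt(oe_up, base)
  }
})

fixed_cohort <- function(seed = 3, n = 6, k = 3, shift = 0.01) {
  set.seed(seed)
  y <- matrix(stats::rnorm(2 * n * k, 0.03, 0.03), 2 * n, k)
  y[1:n, ] <- y[1:n, ] + shift
  grp <- factor(rep(c("RUSI", "Palpation"), each = n))
  list(y = y, grp = grp,
       long = data.frame(participant = rep(seq_len(2 * n), k),
                         group = rep(grp, k),
                         repetition = rep(seq_len(k), each = 2 * n),
                         PAR = as.vector(y)))
}

test_that("mixed-design ANOVA matches the base-R reference to 3 decimals", {
  fc <- fixed_cohort()
  mine <- rm_anova(fc$long)
  ref <- stats::aov(PAR ~ group * factor(repetition) +
                      Error(factor(participant) / factor(repetition)),
                    data = fc$long)
  s <- summary(ref)
  between <- s[[1]][[1]]
  within <- s[[2]][[1]]
  eff <- mine$effects
  expect_equal(eff$F[eff$effect == "group"], between["group", "F value"],
               tolerance = 5e-4)
  expect_equal(eff$p[eff$effect == "group"], between["group", "Pr(>F)"],
               tolerance = 5e-4)
  expect_equal(eff$F[eff$effect == "repetition"],
               within["factor(repetition)", "F value"], tolerance = 5e-4)
  expect_equal(eff$F[eff$effect == "group:repetition"],
               within["group:factor(repetition)", "F value"],
               tolerance = 5e-4)
  expect_equal(eff$p[eff$effect == "group:repetition"],
               within["group:factor(repetition)", "Pr(>F)"],
               tolerance = 5e-4)
  # partial eta^2 from the reference sums of squares
  ss_int <- within["group:factor(repetition)", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  expect_equal(eff$partial_eta_sq[eff$effect == "group:repetition"],
               ss_int / (ss_int + ss_err), tolerance = 1e-6)
})

test_that("all-equal responses give F = 0 and dropped rows are counted", {
  d <- data.frame(participant = rep(1:6, 3),
                  group = rep(rep(c("A", "B"), each = 3), 3),
                  repetition = rep(1:3, each = 6), PAR = 0.02)
  r <- rm_anova(d)
  expect_equal(r$effects$F, rep(0, 3))
  d2 <- d
  d2$PAR <- d2$PAR + stats::rnorm(18, 0, 0.01)
  d2$PAR[d2$participant == 2 & d2$repetition == 3] <- NA
  r2 <- rm_anova(d2)
  expect_identical(r2$n_dropped, 1L)
  expect_identical(r2$n, 5L)
})

test_that("Mauchly's test matches stats::mauchly.test to 3 decimals", {
  fc <- fixed_cohort()
  mine <- mauchly_test(fc$y, group = fc$grp)
  mlm <- stats::lm(fc$y ~ fc$grp)
  ref <- stats::mauchly.test(mlm, X = ~1,
                             idata = data.frame(rep = factor(1:3)))
  expect_equal(mine$W, unname(ref$statistic), tolerance = 5e-4)
  expect_equal(mine$p, ref$p.value, tolerance = 5e-4)
  expect_identical(mine$df, 2L)

  two <- mauchly_test(fc$y[, 1:2], group = fc$grp)
  expect_true(two$trivial)
  expect_equal(two$W, 1)
  expect_equal(two$p, 1)
})

test_that("Greenhouse-Geisser epsilon matches anova.mlm and the branch fires", {
  fc <- fixed_cohort()
  mlm <- stats::lm(fc$y ~ fc$grp)
  printed <- utils::capture.output(
    stats::anova(mlm, X = ~1, idata = data.frame(rep = factor(1:3)),
                 test = "Spherical"))
  gg_line <- grep("Greenhouse-Geisser epsilon", printed, value = TRUE)
  gg_ref <- as.numeric(sub(".*epsilon:\\s*", "", gg_line))
  mine <- rm_anova(fc$long)
  expect_equal(mine$gg_epsilon, gg_ref, tolerance = 5e-4)
  expect_false(mine$gg_applied)  # sphericity met on this cohort

  # strongly non-spherical data must trigger the correction
  set.seed(12)
  n <- 14
  base <- stats::rnorm(n, 0, 0.005)
  y <- cbind(base + stats::rnorm(n, 0, 1e-4),
             base + stats::rnorm(n, 0, 1e-4),
             stats::rnorm(n, 0, 0.08))
  long <- data.frame(participant = rep(1:n, 3),
                     group = rep(rep(c("A", "B"), each = n / 2), 3),
                     repetition = rep(1:3, each = n),
                     PAR = abs(as.vector(y)) + 0.001)
  r <- rm_anova(long)
  expect_lte(r$mauchly$p, 0.05)
  expect_true(r$gg_applied)
  expect_lt(r$effects$df2[r$effects$effect == "repetition"],
            (n - 2) * 2)  # corrected df are smaller
})

test_that("Mauchly rarely rejects under compound symmetry", {
  set.seed(7)
  k <- 3L; n <- 20L
  p_vals <- replicate(200, {
    subj <- stats::rnorm(n, 0, 0.02)
    y <- matrix(stats::rnorm(n * k, 0, 0.02), n, k) + subj
    mauchly_test(y)$p
  })
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("paired t equals the closed form and flags degenerate input", {
  a <- c(0.021, 0.034, 0.055, 0.012, 0.040)
  b <- c(0.018, 0.030, 0.049, 0.020, 0.031)
  mine <- paired_t(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_identical(mine$df, 4L)
  expect_equal(mine$d, mean(a - b) / stats::sd(a - b), tolerance = 1e-12)

  expect_equal(paired_t(c(1, 2, 3, 4), c(0, 3, 2, 5))$t, 0)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("Mann-Whitney U conventions and exact enumeration", {
  expect_equal(mann_whitney_u(c(7, 8, 9), c(1, 2, 3))$U, 0)
  same <- c(1.2, 3.4, 5.6)
  expect_equal(mann_whitney_u(same, same)$U1, length(same)^2 / 2)

  a <- c(1.1, 2.3, 4.5, 6.7)
  b <- c(0.5, 3.3, 5.5, 8.8)
  mine <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_equal(mine$U1, unname(ref$statistic))
  # independent enumeration over all 70 assignments of 8 ranks
  pooled <- c(a, b)
  combos <- utils::combn(8, 4)
  u_all <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - 4 * 5 / 2)
  u_obs <- sum(rank(pooled)[1:4]) - 10
  p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(mine$p, p_enum, tolerance = 1e-9)

  big_a <- stats::rnorm(30); big_b <- stats::rnorm(30, 0.5)
  approx_res <- mann_whitney_u(big_a, big_b)
  ref2 <- stats::wilcox.test(big_a, big_b, exact = FALSE, correct = TRUE)
  expect_equal(approx_res$p, ref2$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("report tables match hand arithmetic and flag n = 1", {
  pt <- data.frame(
    participant = rep(c("P1", "P2"), each = 3),
    group = rep(c("RUSI", "Palpation"), each = 3),
    exercise = "ADIM", repetition = rep(1:3, 2),
    OE_R = 5, OI_R = 9, TrA_R = c(4.0, 4.2, 4.4, 4.6, 4.8, 5.0),
    OE_C = 5, OI_C = 9, TrA_C = c(5.0, 5.2, 5.4, 5.6, 5.8, 6.0))
  pt <- par_table(pt)
  rep1 <- pt$PAR[pt$repetition == 1]
  reports <- build_reports(pt)
  row <- reports$par_summary[
    reports$par_summary$group == "All participants" &
      reports$par_summary$repetition == "1", ]
  expect_equal(row$mean, mean(rep1), tolerance = 1e-12)
  expect_equal(row$sd, stats::sd(rep1), tolerance = 1e-12)
  half <- stats::qt(0.975, 1) * stats::sd(rep1) / sqrt(2)
  expect_equal(row$ci_high - row$mean, half, tolerance = 1e-9)

  solo <- reports$par_summary[reports$par_summary$group == "RUSI" &
                                reports$par_summary$repetition == "1", ]
  expect_identical(solo$n, 1L)
  expect_match(solo$flag, "undefined")
  expect_error(build_reports(pt[0, ]), "empty")
})

test_that("pooled PAR mean of a simulated cohort is near its target", {
  set.seed(42)
  d <- simulate_par_cohort(n_per_group = 6L, mean_par = 0.03,
                           sd_between = 0.03, sd_within = 0.001)
  reports <- build_reports(cbind(d, OE_R = 5, OI_R = 9, TrA_R = 4.6,
                                 OE_C = 5, OI_C = 9, TrA_C = 5.4)[
                                   , c("participant", "group", "exercise",
                                       "repetition", "OE_R", "OI_R",
                                       "TrA_R", "OE_C", "OI_C", "TrA_C",
                                       "PAR")])
  pooled <- reports$par_summary[
    reports$par_summary$group == "All participants" &
      reports$par_summary$repetition == "1 to 3", ]
  se <- 0.03 / sqrt(12)
  expect_lt(abs(pooled$mean - 0.03), 3 * se)
})
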