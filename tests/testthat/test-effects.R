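table1 <- contingency_counts(n11 = 3042, n10 = 12119, n01 = 5221,
                             n00 = 28111)

test_that("tabulation counts the four outcome combinations", {
  pairs <- data.table(treated_focal_bought = c(TRUE, FALSE),
                      control_focal_bought = c(FALSE, FALSE))
  ct <- tabulate_pairs(pairs)
  expect_equal(c(ct$n11, ct$n10, ct$n01, ct$n00), c(0, 1, 0, 1))
  expect_equal(ct$n, 2)
  empty <- tabulate_pairs(pairs[0])
  expect_true(empty$empty)
  # recount by explicit loop over a simulated set of pairs
  set.seed(9)
  p2 <- data.table(treated_focal_bought = runif(100) < 0.4,
                   control_focal_bought = runif(100) < 0.2)
  ct2 <- tabulate_pairs(p2)
  n <- c(0, 0, 0, 0)
  for (i in 1:100) {
    t <- p2$treated_focal_bought[i]; c <- p2$control_focal_bought[i]
    if (t && c) n[1] <- n[1] + 1 else if (t) n[2] <- n[2] + 1
    else if (c) n[3] <- n[3] + 1 else n[4] <- n[4] + 1
  }
  expect_equal(c(ct2$n11, ct2$n10, ct2$n01, ct2$n00), n)
  expect_equal(table1$n, 48493)
})

test_that("risk difference and risk ratio follow the paired definitions", {
  est <- estimate_effect(table1, boot_reps = 2000, seed = 10)
  expect_equal(round(100 * est$rd, 2), 14.22)
  expect_equal(round(est$rr, 2), 1.83)
  expect_equal(round(100 * (est$rr - 1), 2), 83.48)
  expect_equal(round(100 * est$treated_share, 2), 31.26)
  expect_equal(round(100 * est$control_share, 2), 17.04)
  expect_equal(round(est$discordant_ratio, 1), 2.3)
  expect_equal(round(100 * table1$shares[["n10"]]), 25)
  expect_equal(round(100 * table1$shares[["n01"]]), 11)
  # CIs contain the point estimates
  expect_true(est$ci_rd[1] <= est$rd && est$rd <= est$ci_rd[2])
  expect_true(est$ci_rr[1] <= est$rr && est$rr <= est$ci_rr[2])

  # hand arithmetic on small tables
  e2 <- estimate_effect(contingency_counts(0, 4, 1, 5), boot_reps = 50,
                        seed = 1)
  expect_equal(e2$rd, 0.3)
  expect_equal(e2$rr, 4)
  e3 <- estimate_effect(contingency_counts(2, 7, 7, 4), boot_reps = 50,
                        seed = 1)
  expect_equal(e3$rd, 0)
  # no control-side purchases: rr undefined, rd still present
  e4 <- estimate_effect(contingency_counts(0, 4, 0, 6), boot_reps = 50,
                        seed = 1)
  expect_true(is.na(e4$rr))
  expect_equal(e4$rd, 0.4)
  expect_error(estimate_effect(contingency_counts(0, 0, 0, 0)),
               class = "qmimic_param_error")
})

test_that("rd times n is exactly the discordant difference", {
  set.seed(3)
  for (i in 1:25) {
    cnt <- as.list(rmultinom(1, sample(20:500, 1), c(.2, .3, .2, .3))[, 1])
    ct <- contingency_counts(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]])
    est <- estimate_effect(ct, boot_reps = 10, seed = i)
    expect_equal(est$rd * ct$n, ct$n10 - ct$n01)
  }
})

test_that("concordant pairs shrink rd towards 0 and rr towards 1", {
  base <- estimate_effect(contingency_counts(10, 40, 10, 40),
                          boot_reps = 10, seed = 1)
  more <- estimate_effect(contingency_counts(60, 40, 10, 90),
                          boot_reps = 10, seed = 1)
  expect_lt(abs(more$rd), abs(base$rd))
  expect_lt(abs(more$rr - 1), abs(base$rr - 1))
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  small <- estimate_effect(contingency_counts(30, 121, 52, 281),
                           boot_reps = 1500, seed = 5)
  big <- estimate_effect(contingency_counts(304, 1212, 522, 2811),
                         boot_reps = 1500, seed = 5)
  w_small <- diff(small$ci_rd)
  w_big <- diff(big$ci_rd)
  expect_lt(w_big, 0.45 * w_small)   # expect about sqrt(10) ~ 3.2x
  expect_gt(w_big, 0.2 * w_small)
})

test_that("the paired chi-squared test matches its closed form and oracle", {
  ch <- paired_chi2(table1)
  expect_equal(ch$statistic, (12119 - 5221)^2 / 17340)
  expect_equal(round(ch$statistic, 1), 2744.1)
  expect_lt(ch$p_value, 1e-12)
  # independent oracle: stats::mcnemar.test without continuity correction
  m <- matrix(c(3042, 12119, 5221, 28111), 2)
  or <- stats::mcnemar.test(m, correct = FALSE)
  expect_equal(ch$statistic, unname(or$statistic))
  # balanced discordant counts
  ch2 <- paired_chi2(contingency_counts(3, 5, 5, 9))
  expect_equal(ch2$statistic, 0)
  expect_equal(ch2$p_value, 1)
  # invariant to swapping the concordant cells
  a <- paired_chi2(contingency_counts(1, 30, 12, 99))
  b <- paired_chi2(contingency_counts(99, 30, 12, 1))
  expect_equal(a$statistic, b$statistic)
  # exact binomial and chi-squared p converge as discordant counts grow
  ch3 <- paired_chi2(contingency_counts(0, 130, 95, 0))
  expect_lt(abs(ch3$p_exact - ch3$p_value) / ch3$p_value, 0.2)
  ch4 <- paired_chi2(contingency_counts(0, 1300, 950, 0))
  expect_lt(abs(log(ch4$p_exact / ch4$p_value)),
            abs(log(ch3$p_exact / ch3$p_value)))
  # no discordant pairs: undefined sentinel
  expect_true(is.na(paired_chi2(contingency_counts(5, 0, 0, 5))$statistic))
})

test_that("degenerate subgroup axes reproduce the pooled estimate", {
  pairs <- data.table(
    partner_user = rep("P1", 40),
    treated_focal_user = rep("F1", 40), control_focal_user = rep("F1", 40),
    treated_date = as.Date("2018-05-01"), control_date = as.Date("2018-05-02"),
    treated_focal_bought = rep(c(TRUE, FALSE), c(18, 22)),
    control_focal_bought = rep(c(TRUE, FALSE, TRUE, FALSE), c(6, 12, 4, 18)))
  demo <- data.table(user_id = c("P1", "F1"),
                     status = c("student", "student"),
                     gender = c("female", "male"),
                     birth_year = c(1996L, 1985L))
  sub <- subgroup_estimates(pairs, demo, "partner_status", boot_reps = 50,
                            seed = 2)
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$level, "student")
  pooled <- estimate_effect(tabulate_pairs(pairs), boot_reps = 50, seed = 2)
  expect_equal(sub$rd, pooled$rd)
  expect_false(sub$low_n)
  # age terciles at the transaction date: 1996 -> 22 (youngest),
  # 1985 -> 33 (oldest)
  subp <- subgroup_estimates(pairs, demo, "partner_age_tercile",
                             boot_reps = 50, seed = 2)
  expect_equal(subp$level, "<=22")
  subf <- subgroup_estimates(pairs, demo, "focal_age_tercile",
                             boot_reps = 50, seed = 2)
  expect_equal(subf$level, ">32")
  combo <- subgroup_estimates(pairs, demo, "dyad_status_combo",
                              boot_reps = 50, seed = 2)
  expect_equal(combo$level, "student-student")
  # users missing from demographics become an explicit unknown level
  sub_u <- subgroup_estimates(pairs, demo[user_id != "P1"],
                              "partner_status", boot_reps = 50, seed = 2)
  expect_equal(sub_u$level, "unknown")
  expect_error(subgroup_estimates(pairs, demo, "shoe_size"),
               class = "qmimic_param_error")
})

test_that("pairs with discordant focal attributes are dropped and counted", {
  pairs <- data.table(
    partner_user = rep("P1", 35),
    treated_focal_user = rep(c("F1", "F2"), c(30, 5)),
    control_focal_user = rep("F1", 35),
    treated_date = as.Date("2018-05-01"), control_date = as.Date("2018-05-02"),
    treated_focal_bought = rep(TRUE, 35),
    control_focal_bought = rep(FALSE, 35))
  demo <- data.table(user_id = c("P1", "F1", "F2"),
                     status = c("staff", "student", "staff"),
                     gender = c("female", "male", "male"),
                     birth_year = c(1970L, 1995L, 1992L))
  sub <- subgroup_estimates(pairs, demo, "focal_status", boot_reps = 50,
                            seed = 3)
  expect_equal(attr(sub, "n_dropped_discordant"), 5L)
  expect_equal(sub$n_pairs, 30L)
})

test_that("planted subgroup effects are recovered in the right order", {
  cfg <- sim_config(n_users = 300, n_days = 50,
                    status_mix = c(student = 0.5, staff = 0.5, other = 0),
                    subgroup_deltas = c(student = 0.25, staff = 0.05),
                    context_sd = 0.3, seed = 77)
  sim <- simulate_purchase_log(cfg)
  an <- analyze_log(sim$log, sim$catalog, boot_reps = 100, seed = 6)
  sub <- subgroup_estimates(an$pairs, sim$demographics, "focal_status",
                            boot_reps = 100, seed = 7)
  rd_student <- sub[level == "student"]$rd
  rd_staff <- sub[level == "staff"]$rd
  expect_gt(rd_student, rd_staff)
  expect_gt(rd_student, 0.15)
  expect_lt(rd_staff, 0.15)
})
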