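test_that("popularity index is the stratum fraction, recounted by brute force", {
  cat <- tiny_catalog()
  # 10 lunch transactions, 3 contain fruit
  log <- rbindlist(lapply(1:10, function(i)
    txn_row(sprintf("T%02d", i), sprintf("u%d", i),
            sprintf("12:%02d:00", i),
            if (i <= 3) "M1;FRU" else "M1")))
  pop <- build_popularity_index(log, cat, labels = "fruit")
  expect_equal(nrow(pop), 1L)
  expect_equal(pop$popularity, 0.30)
  expect_equal(pop$n_txns, 10L)
  # an item never sold in the stratum is unavailable
  pop2 <- build_popularity_index(log, cat, labels = "dessert")
  expect_equal(pop2$n_contain, 0L)
  # brute-force recount on a random 50-row fixture
  rlog <- random_fixture_log(50, seed = 6)
  an <- annotate_transactions(rlog, cat)
  pop3 <- build_popularity_index(rlog, cat, labels = c("fruit", "dessert"))
  for (r in seq_len(nrow(pop3))) {
    sub <- an[shop_id == pop3$shop_id[r] & date == pop3$date[r] &
                period == pop3$period[r] & !is.na(period)]
    codes <- if (pop3$label[r] == "fruit") "FRU" else "DES"
    want <- mean(vapply(strsplit(sub$items, ";"),
                        function(x) codes %in% x, TRUE))
    expect_equal(pop3$popularity[r], want)
  }
})

test_that("a minimal treated/control pair matches within the caliper", {
  cat <- tiny_catalog()
  dy <- rbind(
    make_dyad("d1", "P", "F", "M1;CON", "M1;CON", "2020-03-02"),
    make_dyad("d2", "P", "F", "M1", "M1", "2020-03-03"))
  pop <- rbind(pop_row("condiment", "2020-03-02", 0.20),
               pop_row("condiment", "2020-03-03", 0.21))
  pr <- match_pairs(dy, "condiment", "lunch", pop, cat, pop_loo = FALSE,
                    seed = 1)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$treated_dyad, "d1")
  expect_equal(pr$control_dyad, "d2")
  expect_true(pr$treated_focal_bought)
  expect_false(pr$control_focal_bought)
  # 0.20 vs 0.25 is 25% apart in relative terms: no pair
  pop2 <- rbind(pop_row("condiment", "2020-03-02", 0.20),
                pop_row("condiment", "2020-03-03", 0.25))
  expect_equal(nrow(match_pairs(dy, "condiment", "lunch", pop2, cat,
                                pop_loo = FALSE, seed = 1)), 0L)
  # but an absolute caliper of 0.10 admits it
  expect_equal(nrow(match_pairs(dy, "condiment", "lunch", pop2, cat,
                                caliper_mode = "absolute",
                                pop_loo = FALSE, seed = 1)), 1L)
  expect_error(match_pairs(dy, "condiment", "lunch", pop, cat, caliper = 0),
               class = "qmimic_param_error")
  expect_error(match_pairs(dy, "condiment", "lunch", pop, cat, caliper = 1.3),
               class = "qmimic_param_error")
})

test_that("different partners, shops or unavailable strata never match", {
  cat <- tiny_catalog()
  dy <- rbind(
    make_dyad("d1", "P", "F", "M1;CON", "M1", "2020-03-02"),
    make_dyad("d2", "Q", "F", "M1", "M1", "2020-03-03"),        # other partner
    make_dyad("d3", "P", "F", "M1", "M1", "2020-03-04", shop = "S2"),
    make_dyad("d4", "P", "F", "M1", "M1", "2020-03-05"))        # unavailable
  pop <- rbind(pop_row("condiment", "2020-03-02", 0.20),
               pop_row("condiment", "2020-03-03", 0.20),
               pop_row("condiment", "2020-03-04", 0.20, shop = "S2"),
               pop_row("condiment", "2020-03-05", 0.00))
  pr <- match_pairs(dy, "condiment", "lunch", pop, cat, pop_loo = FALSE,
                    seed = 1)
  expect_equal(nrow(pr), 0L)
})

test_that("exact-anchor matching requires identical refined anchors", {
  cat <- tiny_catalog()
  dy <- rbind(
    make_dyad("d1", "P", "F", "MV;CON", "MV", "2020-03-02",
              partner_anchor = "meal_veg", focal_anchor = "meal_veg"),
    make_dyad("d2", "P", "F", "M1", "M1", "2020-03-03",
              partner_anchor = "meal_std", focal_anchor = "meal_std"),
    make_dyad("d3", "P", "F", "MV", "MV", "2020-03-04",
              partner_anchor = "meal_veg", focal_anchor = "meal_veg"))
  pop <- rbind(pop_row("condiment", "2020-03-02", 0.20),
               pop_row("condiment", "2020-03-03", 0.20),
               pop_row("condiment", "2020-03-04", 0.20))
  loose <- match_pairs(dy, "condiment", "lunch", pop, cat,
                       pop_loo = FALSE, seed = 1)
  expect_equal(nrow(loose), 1L)
  expect_equal(loose$control_dyad, "d2")  # earliest admissible control
  strict <- match_pairs(dy, "condiment", "lunch", pop, cat,
                        exact_anchor = TRUE, pop_loo = FALSE, seed = 1)
  expect_equal(nrow(strict), 1L)
  expect_equal(strict$control_dyad, "d3")  # only veg-anchored control left
})

test_that("greedy matching attains the optimal size on small instances", {
  cat <- tiny_catalog()
  build_instance <- function(seed, nt, nc) {
    set.seed(seed)
    pt <- round(runif(nt, 0.05, 0.6), 2)
    pc <- round(runif(nc, 0.05, 0.6), 2)
    dates <- sprintf("2020-03-%02d", seq_len(nt + nc))
    dy <- rbindlist(c(
      lapply(seq_len(nt), function(i)
        make_dyad(paste0("t", i), "P", "F", "M1;CON", "M1", dates[i],
                  ts = sprintf("12:%02d:00", i))),
      lapply(seq_len(nc), function(i)
        make_dyad(paste0("c", i), "P", "F", "M1", "M1", dates[nt + i],
                  ts = sprintf("12:%02d:00", nt + i)))))
    pop <- rbindlist(lapply(seq_len(nt + nc), function(i)
      pop_row("condiment", dates[i], c(pt, pc)[i])))
    list(dy = dy, pop = pop, pt = pt, pc = pc)
  }
  grid <- expand.grid(seed = c(1, 5, 9, 14), nt = c(4, 6), nc = c(5, 9))
  ratios <- vapply(seq_len(nrow(grid)), function(g) {
    ins <- build_instance(grid$seed[g], grid$nt[g], grid$nc[g])
    pr <- match_pairs(ins$dy, "condiment", "lunch", ins$pop, cat,
                      pop_loo = FALSE, seed = 2)
    adj <- outer(ins$pt, ins$pc, function(a, b)
      abs(a - b) <= 0.10 * pmax(a, b))
    opt <- optimal_match_size(adj)
    if (opt == 0L) return(1)
    nrow(pr) / opt
  }, 0)
  expect_true(all(ratios >= 0.9))
  expect_gte(mean(ratios == 1), 0.75)  # equality on most fixtures
})

test_that("matched pairs pass an independent predicate re-check", {
  sim <- simulate_purchase_log(sim_config(n_users = 150, n_days = 30,
                                          seed = 23))
  an <- analyze_log(sim$log, sim$catalog, boot_reps = 50, seed = 2)
  pr <- an$pairs
  expect_gt(nrow(pr), 100)
  # injectivity within each item analysis
  expect_false(any(duplicated(pr[, .(item, period, treated_dyad)])))
  expect_false(any(duplicated(pr[, .(item, period, control_dyad)])))
  # caliper respected
  expect_true(all(abs(pr$pop_treated - pr$pop_control) <=
                    0.10 * pmax(pr$pop_treated, pr$pop_control) + 1e-12))
  # shared keys and real treatment contrast, re-derived from the dyads
  dkey <- an$dyads[, .(focal_txn_id, pu = partner_user, sh = shop_id,
                       pe = period, pit = partner_items)]
  m <- merge(pr[, .(item, period, treated_dyad, control_dyad)],
             dkey, by.x = "treated_dyad", by.y = "focal_txn_id")
  m <- merge(m, dkey, by.x = "control_dyad", by.y = "focal_txn_id",
             suffixes = c("_t", "_c"))
  expect_true(all(m$pu_t == m$pu_c))
  expect_true(all(m$sh_t == m$sh_c))
  expect_true(all(m$pe_t == m$pe_c))
  set.seed(1)
  for (r in sample(nrow(m), min(nrow(m), 200))) {
    codes <- qmimic:::focus_codes(sim$catalog, m$item[r])
    expect_true(any(strsplit(m$pit_t[r], ";")[[1]] %in% codes))
    expect_false(any(strsplit(m$pit_c[r], ";")[[1]] %in% codes))
  }
})

test_that("shrinking the caliper never increases the matched count", {
  sim <- simulate_purchase_log(sim_config(n_users = 120, n_days = 25,
                                          seed = 41))
  dy <- filter_frequent_pairs(extract_dyads(sim$log, sim$catalog))
  pop <- build_popularity_index(sim$log, sim$catalog)
  sizes <- vapply(c(0.02, 0.05, 0.10, 0.30, 1.0), function(cal)
    nrow(match_pairs(dy, "condiment", "lunch", pop, sim$catalog,
                     caliper = cal, seed = 3)), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("balance reports SMD before and after matching", {
  # hand-computable 4-pair fixture
  pairs <- data.table(pop_treated = c(0.2, 0.3, 0.25, 0.25),
                      pop_control = c(0.19, 0.29, 0.26, 0.24))
  elig <- data.table(dyad = as.character(1:8),
                     treated = rep(c(TRUE, FALSE), each = 4),
                     popularity = c(0.2, 0.3, 0.25, 0.25,
                                    0.19, 0.29, 0.26, 0.24))
  b <- balance(pairs, eligible = elig)
  num <- abs(mean(pairs$pop_treated) - mean(pairs$pop_control))
  den <- sqrt((var(pairs$pop_treated) + var(pairs$pop_control)) / 2)
  expect_equal(b$smd_after, num / den)
  expect_equal(b$smd_before, num / den)  # same values by construction
  expect_true(b$pass)
  # identical popularity: SMD 0 without degeneracy complaints
  same <- data.table(pop_treated = rep(0.2, 3), pop_control = rep(0.2, 3))
  b2 <- balance(same, eligible = elig)
  expect_equal(b2$smd_after, 0)
  expect_false(b2$degenerate_after)
  # equal SDs but different means with zero variance: degenerate
  d3 <- data.table(pop_treated = rep(0.3, 3), pop_control = rep(0.2, 3))
  b3 <- balance(d3, eligible = elig)
  expect_true(b3$degenerate_after)
})

test_that("a synthetic run is balanced after matching at the 0.10 caliper", {
  sim <- simulate_purchase_log(sim_config(n_users = 200, n_days = 40,
                                          seed = 19))
  an <- analyze_log(sim$log, sim$catalog, boot_reps = 50, seed = 4)
  expect_lt(an$balance$smd_after, 0.2)
  expect_true(an$balance$pass)
})

test_that("matching is unbiased when no shared-context shock exists", {
  # with the day-by-shop shock off, popularity carries no confounding
  # signal and the matched estimate should recover the planted effect
  sim <- simulate_purchase_log(sim_config(n_users = 300, n_days = 60,
                                          context_sd = 0, seed = 71))
  an <- analyze_log(sim$log, sim$catalog, boot_reps = 500, seed = 72)
  rds <- ground_truth_rd(sim$truth)
  expect_gt(rds, an$pooled_estimate$ci_rd[1] - 0.01)
  expect_lt(rds, an$pooled_estimate$ci_rd[2] + 0.01)
})
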