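#' Item catalog used by the synthetic generator
#'
#' Two meal codes (standard and vegetarian), the two anchor beverages,
#' and the seven addition items.
#'
#' @return A `qm_catalog`.
#' @export
sim_catalog <- function() {
  as_catalog(data.frame(
    item_code = c("MEAL_STD", "MEAL_VEG", "COFFEE", "TEA", "CONDIMENT",
                  "SALAD", "PASTRY", "DESSERT", "SOUP", "SOFT_DRINK",
                  "FRUIT"),
    category = c("meal", "meal", "coffee", "tea", "condiment", "salad",
                 "pastry", "dessert", "soup", "soft_drink", "fruit"),
    vegetarian_flag = c("no", "yes", "na", "na", "na", "na", "na", "na",
                        "na", "na", "na")))
}

sim_addition_codes <- function() {
  c(condiment = "CONDIMENT", salad = "SALAD", pastry = "PASTRY",
    dessert = "DESSERT", soup = "SOUP", soft_drink = "SOFT_DRINK",
    fruit = "FRUIT")
}

# Baseline popularity of each addition per period; NA = not on offer.
sim_base_pop <- function() {
  data.table(
    label = rep(names(sim_addition_codes()), 3),
    period = rep(c("breakfast", "lunch", "afternoon"),
                 each = length(sim_addition_codes())),
    base_pop = c(
      NA, NA, 0.25, 0.05, NA, NA, 0.08,          # breakfast
      0.25, 0.15, 0.10, 0.18, 0.10, 0.12, 0.10,  # lunch
      NA, NA, 0.20, 0.08, NA, NA, 0.06))         # afternoon
}

#' Configuration of the synthetic purchase-log generator
#'
#' Defaults emulate the campus-canteen setting the pipeline targets:
#' twelve shops with served registers, three daily meal periods, anchor +
#' addition purchase structure, a mean within-dyad inter-arrival of 14 s,
#' a coffee/tea anchor split of 87/13, recurring co-queueing pairs (so
#' the ten-joint-transactions filter retains plenty of dyads), day-by-shop
#' popularity shocks (shared-context confounding), homophilous tie
#' formation on eating profiles, and an additive mimicry effect `delta`
#' with exponential lag decay of time constant `tau`.
#'
#' @param n_users Number of simulated users.
#' @param n_days Number of simulated days.
#' @param n_shops Number of shops (default 12).
#' @param n_registers Served registers per shop.
#' @param start_date First calendar day of the log.
#' @param status_mix,gender_mix Named probability vectors for user status
#'   (`student`/`staff`/`other`) and gender.
#' @param base_pop Baseline addition popularity per period (data.frame
#'   `label`, `period`, `base_pop`; `NA` = item not offered).
#' @param veg_share Population share of vegetarian meal choices.
#' @param tea_share Share of users whose beverage anchor is tea (the rest
#'   drink coffee), giving a coffee anchor share of about 87%.
#' @param profile_sd Per-user, per-item propensity spread on the log-odds
#'   scale (the "eating profile").
#' @param context_sd SD of the day-by-shop log-odds popularity shock
#'   shared by everyone present (the common environmental factor).
#' @param tie_density Fraction of users belonging to a recurring
#'   co-queueing pair (each user has at most one partner).
#' @param homophily_strength How strongly ties form between users with
#'   similar eating profiles (0 = uniformly random pairing).
#' @param delta Additive mimicry effect: the increase in an addition's
#'   purchase probability when the immediately preceding person at the
#'   register bought it (before lag decay and clipping).
#' @param tau Lag-decay time constant in seconds; `Inf` = no decay.
#' @param subgroup_deltas Optional named vector of per-status `delta`
#'   overrides for the focal (mimicking) user.
#' @param lag_mean Mean within-pair inter-arrival in seconds (default 14).
#' @param attend_prob Named per-period probability that a pair (or a
#'   solo user) visits on a given day.
#' @param anchor_skip_rate Small probability that an arrival buys no
#'   anchor (still occupies a queue slot; cannot join a dyad).
#' @param seed Integer seed; fully determines the simulated log.
#' @return An object of class `qm_sim_config`.
#' @export
sim_config <- function(n_users = 200, n_days = 60, n_shops = 12,
                       n_registers = 2, start_date = "2018-01-08",
                       status_mix = c(student = 0.55, staff = 0.35,
                                      other = 0.10),
                       gender_mix = c(female = 0.57, male = 0.43),
                       base_pop = sim_base_pop(),
                       veg_share = 0.30, tea_share = 0.13,
                       profile_sd = 0.8, context_sd = 0.5,
                       tie_density = 0.8, homophily_strength = 1.5,
                       delta = 0.15, tau = Inf, subgroup_deltas = NULL,
                       lag_mean = 14,
                       attend_prob = c(breakfast = 0.30, lunch = 0.65,
                                       afternoon = 0.20),
                       anchor_skip_rate = 0.02, seed = 1L) {
  cfg <- list(n_users = n_users, n_days = n_days, n_shops = n_shops,
              n_registers = n_registers, start_date = start_date,
              status_mix = status_mix, gender_mix = gender_mix,
              base_pop = as.data.table(base_pop), veg_share = veg_share,
              tea_share = tea_share, profile_sd = profile_sd,
              context_sd = context_sd, tie_density = tie_density,
              homophily_strength = homophily_strength, delta = delta,
              tau = tau, subgroup_deltas = subgroup_deltas,
              lag_mean = lag_mean, attend_prob = attend_prob,
              anchor_skip_rate = anchor_skip_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "qm_sim_config")
}

#' @rdname sim_config
#' @export
default_config <- function() sim_config()

validate_sim_config <- function(cfg) {
  if (cfg$n_users < 2 || cfg$n_days < 1 || cfg$n_shops < 1 ||
      cfg$n_registers < 1)
    qm_config_error("n_users, n_days, n_shops, n_registers must be positive")
  if (cfg$tie_density < 0 || cfg$tie_density > 1)
    qm_config_error("tie_density must lie in [0, 1]: more pairs than users")
  probs <- c(cfg$veg_share, cfg$tea_share, cfg$anchor_skip_rate,
             cfg$attend_prob)
  if (any(probs < 0 | probs > 1))
    qm_config_error("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$status_mix) - 1) > 1e-8 ||
      abs(sum(cfg$gender_mix) - 1) > 1e-8)
    qm_config_error("status_mix and gender_mix must sum to 1")
  if (!all(c("breakfast", "lunch", "afternoon") %in%
           names(cfg$attend_prob)))
    qm_config_error("attend_prob needs breakfast/lunch/afternoon entries")
  bp <- cfg$base_pop$base_pop
  if (any(!is.na(bp) & (bp <= 0 | bp >= 1)))
    qm_config_error("base_pop values must lie in (0, 1)")
  if (cfg$lag_mean <= 0 || cfg$tau <= 0)
    qm_config_error("lag_mean and tau must be positive")
  if (!is.null(cfg$subgroup_deltas) &&
      !all(names(cfg$subgroup_deltas) %in% c("student", "staff", "other")))
    qm_config_error("subgroup_deltas must be named by status")
  invisible(cfg)
}

# Homophilous disjoint pairing: repeatedly take a free user and draw a
# partner among free users with weight exp(strength * similarity), where
# similarity is the negative scaled profile distance.
form_ties <- function(profiles, n_pairs, strength, profile_sd) {
  n <- nrow(profiles)
  free <- sample.int(n)
  pairs <- matrix(0L, n_pairs, 2)
  scale <- if (profile_sd > 0) profile_sd * sqrt(ncol(profiles)) else 1
  for (k in seq_len(n_pairs)) {
    a <- free[1L]
    free <- free[-1L]
    cand <- if (length(free) > 40L) sample(free, 40L) else free
    w <- if (strength > 0 && profile_sd > 0) {
      d <- sqrt(colSums((t(profiles[cand, , drop = FALSE]) - profiles[a, ])^2))
      exp(-strength * d / scale)
    } else rep(1, length(cand))
    b <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
    free <- free[free != b]
    pairs[k, ] <- c(a, b)
  }
  pairs
}

period_bounds_sec <- function() {
  list(breakfast = c(21600, 39600), lunch = c(39600, 52200),
       afternoon = c(52200, 72000))
}

#' Simulate a campus transaction log with known ground truth
#'
#' Generates the full purchase process described in [sim_config()]: tied
#' pairs and solo users arrive at shop registers each period, everyone
#' buys the period anchor (a meal at lunch, coffee or tea otherwise,
#' barring a small anchor-skip rate) and each offered addition
#' independently with probability
#' `logistic(base + profile + context)`, increased additively by
#' `delta * exp(-lag/tau)` when the immediately preceding transaction at
#' the register (same day and period) contained the item. For every
#' decision made behind a predecessor, the counterfactual purchase
#' probabilities with and without exposure are recorded, yielding the
#' analytic target `rd*` via [ground_truth_rd()]. Probabilities pushed
#' above 1 are clipped and counted.
#'
#' @param config A `qm_sim_config`.
#' @return List with elements `log` (transactions in the package's CSV
#'   dialect columns), `truth` (one row per focal decision: item,
#'   exposure, lag, counterfactual probabilities), `demographics`,
#'   `catalog`, `ties`, `clip_rate` and the echoed `config`.
#' @export
simulate_purchase_log <- function(config) {
  stopifnot(inherits(config, "qm_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_users
    add_codes <- sim_addition_codes()
    k <- length(add_codes)
    users <- data.table(
      user_id = sprintf("U%05d", seq_len(n)),
      status = sample(names(cfg$status_mix), n, TRUE, cfg$status_mix),
      gender = sample(names(cfg$gender_mix), n, TRUE, cfg$gender_mix))
    users[, birth_year := fifelse(
      status == "student", sample(1993:2000, n, TRUE),
      fifelse(status == "staff", sample(1958:1988, n, TRUE),
              sample(1950:1995, n, TRUE)))]

    profiles <- matrix(rnorm(n * k, 0, cfg$profile_sd), n, k)
    veg_latent <- rnorm(n, 0, cfg$profile_sd)
    tea_user <- runif(n) < cfg$tea_share

    n_pairs <- floor(cfg$tie_density * n / 2)
    ties <- if (n_pairs > 0)
      form_ties(profiles, n_pairs, cfg$homophily_strength, cfg$profile_sd)
    else matrix(0L, 0, 2)
    paired <- sort(as.vector(ties))
    singles <- setdiff(seq_len(n), paired)
    pair_shop <- sample.int(cfg$n_shops, n_pairs, TRUE)
    single_shop <- sample.int(cfg$n_shops, length(singles), TRUE)

    # scalar day x shop log-odds shock, shared by every item and period:
    # the common environmental factor a day's menu/weather imposes
    ctx <- matrix(rnorm(cfg$n_days * cfg$n_shops, 0, cfg$context_sd),
                  cfg$n_days, cfg$n_shops)

    periods <- c("breakfast", "lunch", "afternoon")
    ap <- cfg$attend_prob[periods]

    visits <- function(ids, shops) {
      if (length(ids) == 0L) return(NULL)
      v <- CJ(idx = seq_along(ids), day = seq_len(cfg$n_days),
              period = periods)
      v <- v[runif(nrow(v)) < ap[period]]
      v[, `:=`(id = ids[idx], shop = shops[idx])]
      v
    }
    pv <- visits(seq_len(n_pairs), pair_shop)
    sv <- visits(singles, single_shop)
    units <- rbind(
      if (!is.null(pv)) pv[, .(day, period, shop, u1 = ties[id, 1],
                               u2 = ties[id, 2])],
      if (!is.null(sv)) sv[, .(day, period, shop, u1 = id,
                               u2 = NA_integer_)])
    if (is.null(units) || nrow(units) == 0L)
      qm_config_error("configuration generates no visits")
    units[, register := sample.int(cfg$n_registers, .N, TRUE)]
    # randomize pair member order, then lay out arrival times per register
    swap <- !is.na(units$u2) & runif(nrow(units)) < 0.5
    tmp <- units$u1[swap]; units$u1[swap] <- units$u2[swap]
    units$u2[swap] <- tmp
    setorder(units, day, shop, period, register)
    pb <- period_bounds_sec()
    # arrival units land uniformly across the service period (a thinned
    # Poisson stream); the tied member follows after an exponential lag
    units[, `:=`(
      pstart = vapply(pb, `[`, 0, 1)[period],
      pend = vapply(pb, `[`, 0, 2)[period],
      lag2 = fifelse(is.na(u2), 0, round(rexp(.N, 1 / cfg$lag_mean))))]
    units[, t1 := round(runif(.N, pstart, pend - 4 * cfg$lag_mean))]
    units[, t2 := pmin(t1 + lag2, pend - 1)]

    txns <- rbind(
      units[, .(day, period, shop, register, t = t1, user = u1)],
      units[!is.na(u2), .(day, period, shop, register, t = t2, user = u2)])
    setorder(txns, day, shop, register, period, t, user)
    nt <- nrow(txns)

    # per-transaction baseline probability for each addition (k x nt)
    base <- cfg$base_pop
    base_lo <- matrix(NA_real_, k, 3,
                      dimnames = list(names(add_codes), periods))
    for (r in seq_len(nrow(base)))
      base_lo[base$label[r], base$period[r]] <-
        if (is.na(base$base_pop[r])) NA_real_ else qlogis(base$base_pop[r])
    pcol <- match(txns$period, periods)
    ctx_txn <- ctx[cbind(txns$day, txns$shop)]
    lo <- base_lo[, pcol, drop = FALSE] +
      t(profiles[txns$user, , drop = FALSE]) +
      matrix(ctx_txn, k, nt, byrow = TRUE)
    P0 <- plogis(lo)
    P0[is.na(P0)] <- 0
    avail <- !is.na(base_lo[, pcol, drop = FALSE])

    delta_u <- if (is.null(cfg$subgroup_deltas)) rep(cfg$delta, nt) else {
      sd_ <- cfg$subgroup_deltas
      d <- sd_[users$status[txns$user]]
      fifelse(is.na(d), cfg$delta, d)
    }

    stream <- paste(txns$day, txns$shop, txns$register, txns$period,
                    sep = "\r")
    new_stream <- c(TRUE, stream[-1] != stream[-nt])
    lag <- c(0, txns$t[-1] - txns$t[-nt])
    decay <- exp(-lag / cfg$tau)

    U <- matrix(runif(nt * k), k, nt)
    B <- matrix(FALSE, k, nt)   # realized addition purchases
    E <- matrix(FALSE, k, nt)   # exposure (predecessor bought item)
    PE <- matrix(NA_real_, k, nt)
    has_prev <- !new_stream
    clipped <- 0L
    n_dec <- 0L
    prev <- rep(FALSE, k)
    for (i in seq_len(nt)) {
      p0 <- P0[, i]
      av <- avail[, i]
      if (new_stream[i]) {
        p <- p0
      } else {
        boost <- delta_u[i] * decay[i]
        raw <- p0 + boost * prev
        clipped <- clipped + sum(raw[av] > 1)
        p <- pmin(1, raw)
        E[, i] <- prev
        PE[, i] <- pmin(1, p0 + boost)
      }
      n_dec <- n_dec + sum(av)
      b <- av & (U[, i] < p)
      B[, i] <- b
      prev <- b
    }

    # anchors and item strings
    skip <- runif(nt) < cfg$anchor_skip_rate
    is_lunch <- txns$period == "lunch"
    veg <- runif(nt) < plogis(qlogis(cfg$veg_share) + veg_latent[txns$user])
    anchor_code <- ifelse(is_lunch, ifelse(veg, "MEAL_VEG", "MEAL_STD"),
                          ifelse(tea_user[txns$user], "TEA", "COFFEE"))
    fallback <- c(breakfast = "PASTRY", lunch = "CONDIMENT",
                  afternoon = "PASTRY")[txns$period]
    items <- vapply(seq_len(nt), function(i) {
      codes <- add_codes[B[, i]]
      if (!skip[i]) codes <- c(anchor_code[i], codes)
      if (!length(codes)) codes <- fallback[i]
      paste(codes, collapse = ";")
    }, "")

    day0 <- as.Date(cfg$start_date)
    ts <- as.POSIXct(day0, tz = "UTC") + (txns$day - 1) * 86400 + txns$t
    ord <- order(ts, txns$shop, txns$register)
    txn_id <- character(nt)
    txn_id[ord] <- sprintf("T%07d", seq_len(nt))
    log <- data.table(
      txn_id = txn_id,
      user_id = users$user_id[txns$user],
      shop_id = sprintf("S%02d", txns$shop),
      register_id = sprintf("R%d", txns$register),
      timestamp = ts,
      items = items)
    setorder(log, shop_id, register_id, timestamp, txn_id)

    tr_rows <- which(has_prev)
    truth <- rbindlist(lapply(seq_len(k), function(j) {
      rows <- tr_rows[avail[j, tr_rows]]
      data.table(focal_txn_id = txn_id[rows],
                 item = names(add_codes)[j],
                 exposed = E[j, rows],
                 lag_seconds = lag[rows],
                 p_unexposed = P0[j, rows],
                 p_exposed = PE[j, rows])
    }))

    list(log = log, truth = truth, demographics = users,
         catalog = sim_catalog(),
         ties = data.table(user_a = users$user_id[ties[, 1]],
                           user_b = users$user_id[ties[, 2]]),
         clip_rate = if (n_dec > 0) clipped / n_dec else 0,
         config = cfg)
  })
}

#' Ground-truth risk difference of a simulation
#'
#' The analytic target `rd*`: the mean, over exposed focal decisions, of
#' the counterfactual purchase probability with exposure minus without.
#' The matched-pipeline RD estimate should recover this quantity, not the
#' raw `delta` (clipping and lag decay separate the two).
#'
#' @param truth The `truth` table from [simulate_purchase_log()].
#' @param item Optional focus label to restrict to.
#' @return Numeric scalar (`NA` if no exposed decisions).
#' @export
ground_truth_rd <- function(truth, item = NULL) {
  tr <- as.data.table(truth)
  if (!is.null(item)) tr <- tr[tr$item %in% item]
  tr <- tr[exposed == TRUE]
  if (nrow(tr) == 0L) return(NA_real_)
  mean(tr$p_exposed - tr$p_unexposed)
}
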