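#' The focus items analysed for mimicry
#'
#' The 13 addition analyses (seven lunch additions: condiment, salad,
#' pastry, dessert, soup, soft drink, fruit; and pastry, dessert, fruit at
#' breakfast and in the afternoon) plus the two anchor-type analyses
#' (vegetarian vs. non-vegetarian meal at lunch; tea vs. coffee in the
#' beverage periods).
#'
#' @param include_anchor_types Include the `vegetarian_meal` and `tea`
#'   analyses (default `TRUE`).
#' @return data.table with columns `label` and `period`.
#' @export
focus_items <- function(include_anchor_types = TRUE) {
  lunch_adds <- c("condiment", "salad", "pastry", "dessert", "soup",
                  "soft_drink", "fruit")
  bev_adds <- c("pastry", "dessert", "fruit")
  out <- rbind(
    data.table(label = lunch_adds, period = "lunch"),
    data.table(label = bev_adds, period = "breakfast"),
    data.table(label = bev_adds, period = "afternoon"))
  if (include_anchor_types)
    out <- rbind(out, data.table(
      label = c("vegetarian_meal", "tea", "tea"),
      period = c("lunch", "breakfast", "afternoon")))
  out[]
}

# Item codes realizing a focus label.
focus_codes <- function(catalog, label) {
  if (label == "vegetarian_meal")
    return(catalog$item_code[catalog$category == "meal" &
                             catalog$vegetarian_flag == "yes"])
  codes_of_category(catalog, label)
}

#' Stratum-level item popularity and availability
#'
#' Popularity of a focus item in a (shop, date, period) stratum is the
#' fraction of *all* transactions in the stratum (anchored or not) whose
#' item set contains the item. An item is considered available in a
#' stratum iff it was bought there at least once -- availability is
#' approximated from sales (see `pop_loo` in [match_pairs()] for how the
#' dyad's own purchases are handled).
#'
#' @param log Transactions (annotated or raw).
#' @param catalog A `qm_catalog`.
#' @param labels Focus labels to index; defaults to all of
#'   [focus_items()]'s labels.
#' @return data.table with columns `shop_id`, `date`, `period`, `label`,
#'   `popularity`, `n_contain`, `n_txns`.
#' @export
build_popularity_index <- function(log, catalog, labels = NULL) {
  log <- as.data.table(log)
  if (nrow(log) == 0L) qm_param_error("empty transaction log")
  if (!"period" %in% names(log)) log <- annotate_transactions(log, catalog)
  if (is.null(labels)) labels <- unique(focus_items()$label)
  strata <- log[!is.na(period)]
  out <- rbindlist(lapply(labels, function(lb) {
    codes <- focus_codes(catalog, lb)
    strata[, {
      nc <- sum(txn_contains(items, codes))
      .(label = lb, popularity = nc / .N, n_contain = nc, n_txns = .N)
    }, by = .(shop_id, date, period)]
  }))
  setorder(out, label, shop_id, date, period)
  out[]
}

smd_value <- function(x, y) {
  num <- abs(mean(x) - mean(y))
  den <- sqrt((var(x) + var(y)) / 2)
  if (!is.finite(den) || den == 0)
    return(list(smd = if (num == 0) 0 else NA_real_,
                degenerate = num != 0))
  list(smd = num / den, degenerate = FALSE)
}

empty_eligible <- function() {
  data.table(dyad = character(), treated = logical(),
             popularity = numeric())
}

caliper_ok <- function(pt, pc, caliper, mode) {
  if (mode == "relative") abs(pt - pc) <= caliper * pmax(pt, pc)
  else abs(pt - pc) <= caliper
}

#' Match treated and control dyads for one focus item
#'
#' Treated dyads are those whose partner's transaction contains the focus
#' item; controls are those whose partner's does not. Pairs are formed
#' one-to-one without replacement so that within a pair: the partner is
#' the same person, the shop and meal period are identical, the item is
#' available (sold at least once) in both dyads' (shop, date, period)
#' strata, and stratum popularity agrees within the caliper. The focal
#' outcome is left entirely free. Matching is greedy: treated dyads in
#' chronological order each take the admissible control with the nearest
#' popularity, ties broken by earliest control transaction, then by a
#' seeded draw. Calendar date is deliberately not an exact key: date
#' information enters through availability and popularity.
#'
#' @param dyads Dyads (after the frequent-pair filter).
#' @param item Focus label, e.g. `"condiment"` or `"vegetarian_meal"`.
#' @param period Meal period of the analysis.
#' @param pop Popularity index from [build_popularity_index()].
#' @param catalog A `qm_catalog`.
#' @param caliper Maximum popularity discrepancy, in (0, 1]; default 0.10.
#' @param caliper_mode `"relative"` (default): admissible when
#'   `|pt - pc| <= caliper * max(pt, pc)`; or `"absolute"`.
#' @param exact_anchor If `TRUE`, treated and control must also share the
#'   identical refined anchors (vegetarian vs. standard meal, coffee vs.
#'   tea) -- the exact-anchor robustness variant.
#' @param pop_loo If `TRUE` (default), both the popularity value the
#'   caliper compares and the availability requirement leave the dyad's
#'   own two transactions out of its stratum. With the moderate stratum
#'   sizes of a single shop-day this matters: judged on raw counts, a
#'   rare item's control stratum is often "available" only because the
#'   focal person bought the item, tying eligibility to the outcome;
#'   `FALSE` restores the raw sold-at-least-once rule.
#' @param seed Integer seed for the final tie-break.
#' @return data.table of matched pairs, one row per pair, with an
#'   `eligible` attribute (the treated/control popularity values of all
#'   eligible dyads) used by [balance()].
#' @export
match_pairs <- function(dyads, item, period, pop, catalog,
                        caliper = 0.10, caliper_mode = c("relative", "absolute"),
                        exact_anchor = FALSE, pop_loo = TRUE, seed = 1L) {
  caliper_mode <- match.arg(caliper_mode)
  if (!is.numeric(caliper) || length(caliper) != 1L ||
      caliper <= 0 || caliper > 1)
    qm_param_error("caliper must be a single number in (0, 1]")
  per <- period
  d <- as.data.table(dyads)[period == per]
  empty <- data.table(
    item = character(), period = character(), partner_user = character(),
    shop_id = character(), treated_dyad = character(),
    control_dyad = character(), treated_focal_user = character(),
    control_focal_user = character(), treated_date = as.Date(character()),
    control_date = as.Date(character()), pop_treated = numeric(),
    pop_control = numeric(), treated_lag = numeric(),
    control_lag = numeric(), treated_focal_bought = logical(),
    control_focal_bought = logical())
  if (nrow(d) == 0L) {
    setattr(empty, "eligible", empty_eligible())
    return(empty)
  }
  codes <- focus_codes(catalog, item)
  d[, treated := txn_contains(partner_items, codes)]
  d[, bought := txn_contains(focal_items, codes)]
  p <- pop[label == item & period == per,
           .(shop_id, date, popularity, n_contain, n_txns)]
  d <- p[d, on = c("shop_id", "date")]
  d <- d[!is.na(n_contain)]
  if (pop_loo) {
    # leave-one-out: the dyad's own two transactions are removed from the
    # stratum before judging availability and popularity, so a dyad is
    # never matched -- or made eligible -- by its own purchases. Without
    # this, a rare item's control stratum is often "available" only
    # because the focal person bought it, a direct outcome leak.
    d[, popularity := (n_contain - treated - bought) / pmax(n_txns - 2, 1)]
    d <- d[popularity > 0]
  } else {
    d <- d[n_contain > 0]   # availability: sold at least once
  }
  if (nrow(d) == 0L) {
    setattr(empty, "eligible", empty_eligible())
    return(empty)
  }
  d[, cell := paste(partner_user, shop_id, sep = "\r")]
  if (exact_anchor)
    d[, cell := paste(cell, partner_anchor_refined, focal_anchor_refined,
                      sep = "\r")]
  eligible <- d[, .(dyad = focal_txn_id, treated, popularity)]

  pairs <- with_seed(seed, {
    rbindlist(lapply(split(seq_len(nrow(d)), d$cell), function(idx) {
      sub <- d[idx]
      t_i <- which(sub$treated)
      c_i <- which(!sub$treated)
      if (!length(t_i) || !length(c_i)) return(NULL)
      t_i <- t_i[order(sub$focal_ts[t_i], sub$focal_txn_id[t_i])]
      used <- rep(FALSE, length(c_i))
      res <- vector("list", length(t_i))
      for (k in seq_along(t_i)) {
        ti <- t_i[k]
        avail <- c_i[!used]
        if (!length(avail)) break
        pt <- sub$popularity[ti]
        adm <- caliper_ok(pt, sub$popularity[avail], caliper, caliper_mode)
        if (!any(adm)) next
        cand <- avail[adm]
        dd <- abs(sub$popularity[cand] - pt)
        cand <- cand[dd == min(dd)]
        if (length(cand) > 1L) {
          ts_c <- sub$focal_ts[cand]
          cand <- cand[ts_c == min(ts_c)]
          if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
        }
        ci <- cand[1L]
        used[match(ci, c_i)] <- TRUE
        res[[k]] <- data.table(
          item = item, period = per,
          partner_user = sub$partner_user[ti], shop_id = sub$shop_id[ti],
          treated_dyad = sub$focal_txn_id[ti],
          control_dyad = sub$focal_txn_id[ci],
          treated_focal_user = sub$focal_user[ti],
          control_focal_user = sub$focal_user[ci],
          treated_date = sub$date[ti], control_date = sub$date[ci],
          pop_treated = sub$popularity[ti], pop_control = sub$popularity[ci],
          treated_lag = sub$lag_seconds[ti],
          control_lag = sub$lag_seconds[ci],
          treated_focal_bought = sub$bought[ti],
          control_focal_bought = sub$bought[ci])
      }
      rbindlist(res)
    }))
  })
  if (is.null(pairs) || nrow(pairs) == 0L) pairs <- empty
  setattr(pairs, "eligible", eligible)
  pairs[]
}

#' Match all focus items and pool the pairs
#'
#' Runs [match_pairs()] for every row of `items` and concatenates the
#' results (the pooled analysis concatenates matched pairs across the
#' per-item analyses before tabulation).
#'
#' @inheritParams match_pairs
#' @param items data.table of `label`/`period` rows, e.g. [focus_items()].
#' @return data.table of matched pairs across all items.
#' @export
match_all_items <- function(dyads, items, pop, catalog, caliper = 0.10,
                            caliper_mode = "relative", exact_anchor = FALSE,
                            pop_loo = TRUE, seed = 1L) {
  res <- lapply(seq_len(nrow(items)), function(i) {
    match_pairs(dyads, items$label[i], items$period[i], pop, catalog,
                caliper = caliper, caliper_mode = caliper_mode,
                exact_anchor = exact_anchor, pop_loo = pop_loo,
                seed = stage_seed(seed, paste(items$label[i], items$period[i])))
  })
  eligible <- rbindlist(lapply(res, attr, "eligible"))
  out <- rbindlist(res)
  setattr(out, "eligible", eligible)
  out[]
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) of stratum popularity between
#' treated and control groups: before matching over all eligible dyads,
#' after matching over the matched pairs. Groups are considered balanced
#' when all post-matching SMDs are below 0.2.
#'
#' @param pairs Matched pairs from [match_pairs()].
#' @param eligible Optional eligibility table (`treated`, `popularity`);
#'   defaults to the `eligible` attribute attached by [match_pairs()].
#' @param threshold Balance threshold (default 0.2).
#' @return List with `smd_before`, `smd_after`, `pass`, `threshold` and
#'   degeneracy flags.
#' @export
balance <- function(pairs, eligible = NULL, threshold = 0.2) {
  if (is.null(eligible)) eligible <- attr(pairs, "eligible")
  if (nrow(pairs) < 2L) qm_param_error("need at least 2 matched pairs")
  after <- smd_value(pairs$pop_treated, pairs$pop_control)
  before <- if (!is.null(eligible) && nrow(eligible) > 0L)
    smd_value(eligible$popularity[eligible$treated],
              eligible$popularity[!eligible$treated])
  else list(smd = NA_real_, degenerate = FALSE)
  list(smd_before = before$smd, smd_after = after$smd,
       pass = isTRUE(after$smd < threshold), threshold = threshold,
       degenerate_before = before$degenerate,
       degenerate_after = after$degenerate)
}
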