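library(data.table)

# Minimal catalog used by hand-built fixtures (generator tests use
# sim_catalog() instead).
tiny_catalog <- function() {
  as_catalog(data.frame(
    item_code = c("M1", "MV", "COF", "TEA", "FRU", "DES", "CON"),
    category = c("meal", "meal", "coffee", "tea", "fruit", "dessert",
                 "condiment"),
    vegetarian_flag = c("no", "yes", "na", "na", "na", "na", "na")))
}

# One transaction row; time given as "HH:MM:SS" on a fixed date.
txn_row <- function(id, user, time, items, shop = "S1", reg = "R1",
                    date = "2020-03-02") {
  data.table(txn_id = id, user_id = user, shop_id = shop, register_id = reg,
             timestamp = as.POSIXct(paste(date, time), tz = "UTC"),
             items = items)
}

# Random small register log for oracle tests: users cycle through one
# register stream with exponential gaps; some transactions unanchored.
random_fixture_log <- function(n, seed, n_users = 6, n_regs = 2) {
  set.seed(seed)
  tt <- cumsum(rexp(n, 1 / 120))
  data.table(
    txn_id = sprintf("X%03d", seq_len(n)),
    user_id = sprintf("u%d", sample.int(n_users, n, TRUE)),
    shop_id = "S1",
    register_id = sprintf("R%d", sample.int(n_regs, n, TRUE)),
    timestamp = as.POSIXct("2020-03-02 11:05:00", tz = "UTC") + tt,
    items = sample(c("M1", "M1;FRU", "M1;DES;CON", "FRU", "DES"),
                   n, TRUE, prob = c(.3, .25, .25, .1, .1)))
}

# Exhaustive-predicate oracle: all ordered transaction pairs satisfying
# every dyad clause, written independently of extract_dyads.
brute_force_dyads <- function(log, catalog, window = 300) {
  an <- annotate_transactions(log, catalog)
  an <- an[order(shop_id, register_id, timestamp, txn_id)]
  out <- list()
  for (i in seq_len(nrow(an))) for (j in seq_len(nrow(an))) {
    a <- an[i]; b <- an[j]
    if (a$shop_id != b$shop_id || a$register_id != b$register_id) next
    lag <- as.numeric(b$timestamp) - as.numeric(a$timestamp)
    if (lag < 0 || lag > window) next
    if (i == j || a$user_id == b$user_id) next
    if (is.na(a$period) || is.na(b$period) || a$period != b$period) next
    if (a$date != b$date) next
    if (is.na(a$anchor) || is.na(b$anchor)) next
    # no transaction strictly between the two at this register
    between <- an[shop_id == a$shop_id & register_id == a$register_id &
                    ((timestamp > a$timestamp & timestamp < b$timestamp) |
                     (timestamp == a$timestamp & txn_id != a$txn_id &
                        txn_id != b$txn_id & timestamp < b$timestamp))]
    # with tied timestamps order follows txn_id; keep the simple strict rule
    ok_adjacent <- {
      stream <- an[shop_id == a$shop_id & register_id == a$register_id]
      ia <- which(stream$txn_id == a$txn_id)
      ib <- which(stream$txn_id == b$txn_id)
      ib == ia + 1L
    }
    if (!ok_adjacent) next
    out[[length(out) + 1L]] <- data.table(partner_txn_id = a$txn_id,
                                          focal_txn_id = b$txn_id)
  }
  if (length(out)) unique(rbindlist(out)) else
    data.table(partner_txn_id = character(), focal_txn_id = character())
}

# Hand-built dyad row with the columns match_pairs() consumes.
make_dyad <- function(id, partner, focal, partner_items, focal_items,
                      date, shop = "S1", period = "lunch", lag = 10,
                      ts = "12:00:00", partner_anchor = "meal_std",
                      focal_anchor = "meal_std") {
  data.table(
    partner_txn_id = paste0("p", id), focal_txn_id = id,
    partner_user = partner, focal_user = focal,
    shop_id = shop, register_id = "R1", date = as.Date(date),
    period = period, lag_seconds = lag,
    partner_anchor = sub("_.*", "", partner_anchor),
    focal_anchor = sub("_.*", "", focal_anchor),
    partner_anchor_refined = partner_anchor,
    focal_anchor_refined = focal_anchor,
    partner_items = partner_items, focal_items = focal_items,
    partner_ts = as.POSIXct(paste(date, "11:59:50"), tz = "UTC"),
    focal_ts = as.POSIXct(paste(date, ts), tz = "UTC"))
}

# Popularity-index row for hand-built matching tests.
pop_row <- function(label, date, popularity, n_txns = 100, shop = "S1",
                    period = "lunch") {
  data.table(shop_id = shop, date = as.Date(date), period = period,
             label = label, popularity = popularity,
             n_contain = round(popularity * n_txns), n_txns = n_txns)
}

# Optimal bipartite matching size by exhaustive recursion (treated side
# assigned one by one), independent of the greedy implementation.
optimal_match_size <- function(adj) {
  nt <- nrow(adj)
  if (nt == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used) {
    if (i > nt) return(0L)
    b <- recurse(i + 1L, used)            # leave treated i unmatched
    for (j in which(adj[i, ])) {
      if (!used[j]) {
        used2 <- used; used2[j] <- TRUE
        b <- max(b, 1L + recurse(i + 1L, used2))
      }
    }
    b
  }
  recurse(1L, rep(FALSE, ncol(adj)))
}
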