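#' Extract partner-focal dyads from a register-ordered log
#'
#' A dyad is two different users paying consecutively at the same shop and
#' register, on the same day and in the same meal period, at most
#' `window_seconds` apart, with no other transaction at that register in
#' between, and with both transactions containing the period-appropriate
#' anchor (a meal at lunch, coffee/tea otherwise). The earlier transaction
#' is the partner, the later one the focal. A transaction may be focal in
#' one dyad and partner in the next (chains are allowed); adjacency is
#' evaluated over *all* transactions, so an unanchored purchase in between
#' still breaks a would-be dyad.
#'
#' @param log Transactions, sorted by timestamp within each
#'   (shop, register) stream; violating that order is an error.
#' @param catalog A `qm_catalog` (used to annotate if needed).
#' @param window_seconds Maximum partner-to-focal gap (default 300 s).
#' @return A data.table, one row per dyad, with both users' ids, item
#'   sets, anchors, the lag in seconds and the stratum keys.
#' @export
extract_dyads <- function(log, catalog, window_seconds = 300) {
  log <- as.data.table(log)
  # order check within each register stream, in the input row order
  ok <- log[, all(diff(as.numeric(timestamp)) >= 0),
            by = .(shop_id, register_id)]$V1
  if (!all(ok))
    qm_order_error("log is not sorted by timestamp within register streams")
  if (!"period" %in% names(log)) log <- annotate_transactions(log, catalog)
  d <- copy(log)
  setorder(d, shop_id, register_id, timestamp, txn_id)
  d[, `:=`(prev_txn   = shift(txn_id),
           prev_user  = shift(user_id),
           prev_ts    = shift(timestamp),
           prev_items = shift(items),
           prev_anchor = shift(anchor),
           prev_anchor_refined = shift(anchor_refined),
           prev_period = shift(period),
           prev_date = shift(date)),
    by = .(shop_id, register_id)]
  d[, lag_seconds := as.numeric(timestamp) - as.numeric(prev_ts)]
  dy <- d[!is.na(prev_txn) &
            user_id != prev_user &
            lag_seconds <= window_seconds &
            date == prev_date &
            !is.na(period) & period == prev_period &
            !is.na(anchor) & !is.na(prev_anchor)]
  out <- dy[, .(partner_txn_id = prev_txn, focal_txn_id = txn_id,
                partner_user = prev_user, focal_user = user_id,
                shop_id, register_id, date, period,
                lag_seconds,
                partner_anchor = prev_anchor, focal_anchor = anchor,
                partner_anchor_refined = prev_anchor_refined,
                focal_anchor_refined = anchor_refined,
                partner_items = prev_items, focal_items = items,
                partner_ts = prev_ts, focal_ts = timestamp)]
  setorder(out, shop_id, register_id, focal_ts, focal_txn_id)
  out[]
}

#' Keep dyads of frequently co-queueing user pairs
#'
#' Retains dyads whose user pair appears at least `min_joint` times in the
#' dyad set, so the same two people are observed repeatedly and the
#' partner's identity can act as a matching key. By default both orderings
#' of a pair are pooled when counting; `ordering = "ordered"` counts
#' (partner, focal) directions separately.
#'
#' @param dyads Output of [extract_dyads()].
#' @param min_joint Minimum number of joint dyads (default 10).
#' @param ordering `"pooled"` (default) or `"ordered"`.
#' @return The retained dyads.
#' @export
filter_frequent_pairs <- function(dyads, min_joint = 10,
                                  ordering = c("pooled", "ordered")) {
  ordering <- match.arg(ordering)
  d <- as.data.table(dyads)
  if (nrow(d) == 0L) return(d)
  key <- if (ordering == "pooled")
    paste(pmin(d$partner_user, d$focal_user),
          pmax(d$partner_user, d$focal_user), sep = "\r")
  else paste(d$partner_user, d$focal_user, sep = "\r")
  cnt <- table(key)
  d[as.vector(cnt[key]) >= min_joint]
}

#' Descriptive summary of a dyad set
#'
#' Reports the dyad count, the mean/SD of the partner-to-focal lag, the
#' fraction of dyads under one minute, and the anchor shares per period
#' (both dyad members pooled) -- the statistics used to sanity-check a
#' synthetic log against real-world queue behaviour.
#'
#' @param dyads Output of [extract_dyads()].
#' @return A list; `n = 0` with `NA` statistics if `dyads` is empty.
#' @export
dyad_summary <- function(dyads) {
  d <- as.data.table(dyads)
  if (nrow(d) == 0L)
    return(list(n = 0L, lag_mean = NA_real_, lag_sd = NA_real_,
                frac_under_60s = NA_real_, anchor_shares = list()))
  anchors <- rbind(d[, .(period, anchor = partner_anchor)],
                   d[, .(period, anchor = focal_anchor)])
  shares <- lapply(split(anchors$anchor, anchors$period),
                   function(a) prop.table(table(a)))
  list(n = nrow(d),
       lag_mean = mean(d$lag_seconds),
       lag_sd = sd(d$lag_seconds),
       frac_under_60s = mean(d$lag_seconds < 60),
       anchor_shares = shares)
}
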