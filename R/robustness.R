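#' Randomized-partner baseline
#'
#' Replaces each dyad's partner transaction by one drawn uniformly at
#' random from the anchored transactions of the same (shop, date, period)
#' stratum, excluding the focal user's own transactions. Downstream
#' matching and estimation are then run unchanged; because the random
#' "partner" did not actually precede the focal person in the queue, any
#' residual association isolates shared-context similarity rather than
#' queue mimicry. The true partner remains eligible for the draw by
#' default (excluding it would bias the null slightly).
#'
#' @param dyads Dyads to randomize.
#' @param log The full transaction log (annotated or raw).
#' @param catalog A `qm_catalog`.
#' @param seed Integer seed.
#' @param exclude_true_partner Also exclude the dyad's actual partner from
#'   the draw (default `FALSE`).
#' @return Dyads with partner fields replaced; dyads whose stratum offers
#'   no eligible replacement are dropped and counted in the
#'   `n_dropped` attribute.
#' @export
randomize_partners <- function(dyads, log, catalog, seed = 1L,
                               exclude_true_partner = FALSE) {
  d <- copy(as.data.table(dyads))
  log <- as.data.table(log)
  if (!"period" %in% names(log)) log <- annotate_transactions(log, catalog)
  pool <- log[!is.na(period) & !is.na(anchor),
              .(txn_id, user_id, items, anchor, anchor_refined,
                shop_id, date, period)]
  pool[, stratum := paste(shop_id, date, period, sep = "\r")]
  pool_split <- split(seq_len(nrow(pool)), pool$stratum)
  d[, stratum := paste(shop_id, date, period, sep = "\r")]
  keep <- logical(nrow(d))
  pick <- integer(nrow(d))
  with_seed(seed, {
    for (i in seq_len(nrow(d))) {
      idx <- pool_split[[d$stratum[i]]]
      if (is.null(idx)) next
      ok <- pool$user_id[idx] != d$focal_user[i]
      if (exclude_true_partner)
        ok <- ok & pool$txn_id[idx] != d$partner_txn_id[i]
      idx <- idx[ok]
      if (!length(idx)) next
      keep[i] <- TRUE
      pick[i] <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }
  })
  n_dropped <- sum(!keep)
  d <- d[keep]
  pk <- pick[keep]
  d[, `:=`(partner_txn_id = pool$txn_id[pk],
           partner_user = pool$user_id[pk],
           partner_items = pool$items[pk],
           partner_anchor = pool$anchor[pk],
           partner_anchor_refined = pool$anchor_refined[pk])]
  d[, stratum := NULL]
  setattr(d, "n_dropped", n_dropped)
  d[]
}

#' Lag-binned dose-response of the mimicry effect
#'
#' Bins matched pairs by the queue lag of the dyad where exposure occurred
#' (the treated dyad by default), re-estimates RD and RR per bin, and fits
#' a weighted least-squares line of the per-bin estimates on the bin
#' midpoints, weighted by bin pair counts. A genuine visual-exposure
#' effect should fade as the two purchases move apart in time, giving a
#' negative slope; a lag-independent confounder would not.
#'
#' @param pairs Matched pairs (needs `treated_lag`/`control_lag`).
#' @param bin_width Bin width in seconds (default 10).
#' @param max_lag Upper lag bound for the fit (default 120 s); pairs
#'   beyond it are pooled into an overflow bin excluded from the fit.
#' @param lag_source `"treated"` (default) or `"mean"` of both dyads.
#' @return List: `bins` (data.table of per-bin mid, n, rd, rr),
#'   `slope_rd`, `p_rd`, `slope_rr`, `p_rr`, `n_overflow`.
#' @export
dose_response <- function(pairs, bin_width = 10, max_lag = 120,
                          lag_source = c("treated", "mean")) {
  lag_source <- match.arg(lag_source)
  p <- copy(as.data.table(pairs))
  if (nrow(p) == 0L) qm_param_error("no matched pairs")
  p[, pair_lag := if (lag_source == "treated") treated_lag
                  else (treated_lag + control_lag) / 2]
  edges <- seq(0, max_lag, by = bin_width)
  p[, bin := findInterval(pair_lag, edges, rightmost.closed = FALSE)]
  n_overflow <- sum(p$pair_lag >= max_lag)
  p <- p[pair_lag < max_lag & pair_lag >= 0]
  bins <- rbindlist(lapply(split(p, p$bin), function(sub) {
    ct <- tabulate_pairs(sub)
    est <- rd_rr_from_counts(ct$n11, ct$n10, ct$n01, ct$n00)
    data.table(bin = sub$bin[1],
               mid = edges[sub$bin[1]] + bin_width / 2,
               n = ct$n, rd = unname(est["rd"]), rr = unname(est["rr"]))
  }))
  if (nrow(bins) < 3L)
    qm_param_error("dose-response fit needs at least 3 non-empty lag bins")
  setorder(bins, mid)
  wls <- function(col) {
    b <- bins[is.finite(bins[[col]])]
    if (nrow(b) < 3L) return(c(NA_real_, NA_real_))
    f <- lm(b[[col]] ~ b$mid, weights = b$n)
    s <- suppressWarnings(summary(f))$coefficients
    c(coef(f)[2], if (nrow(s) > 1 && ncol(s) >= 4) s[2, 4] else NA_real_)
  }
  frd <- wls("rd"); frr <- wls("rr")
  list(bins = bins[],
       slope_rd = unname(frd[1]), p_rd = unname(frd[2]),
       slope_rr = unname(frr[1]), p_rr = unname(frr[2]),
       n_overflow = n_overflow, bin_width = bin_width, max_lag = max_lag)
}

#' Rosenbaum sensitivity bound for a paired binary outcome
#'
#' Quantifies how strong a hidden bias in treatment assignment within
#' matched pairs would need to be to explain away the observed effect.
#' For odds-of-treatment ratio `Gamma`, the one-sided upper-bound p-value
#' of the sign test on the discordant pairs is
#' `P[Binomial(n10 + n01, Gamma/(1 + Gamma)) >= n10]`; at `Gamma = 1`
#' this is the exact binomial p-value under random assignment.
#' `gamma_star` is the smallest `Gamma >= 1` at which the bound crosses
#' `alpha`, located by bisection to 1e-3.
#'
#' @param counts A `qm_counts` object.
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `qm_sensitivity`: `gamma_star`, the bound
#'   function `pbound(gamma)`, `alpha`, and the discordant counts.
#' @export
rosenbaum_gamma <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "qm_counts"))
  n10 <- counts$n10; n01 <- counts$n01
  m <- n10 + n01
  if (m == 0L) qm_param_error("no discordant pairs")
  pbound <- function(gamma) {
    pbinom(n10 - 1, m, gamma / (1 + gamma), lower.tail = FALSE)
  }
  gamma_star <- if (n10 <= n01) 1 else {
    lo <- 1; hi <- 2
    while (pbound(hi) < alpha && hi < 1e6) hi <- hi * 2
    if (pbound(hi) < alpha) Inf else {
      while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        if (pbound(mid) >= alpha) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }
  }
  structure(list(gamma_star = gamma_star, pbound = pbound, alpha = alpha,
                 n10 = n10, n01 = n01),
            class = "qm_sensitivity")
}

#' @export
print.qm_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Rosenbaum sensitivity: gamma* = %.3f at alpha = %g (discordant %d vs %d)\n",
    x$gamma_star, x$alpha, x$n10, x$n01))
  invisible(x)
}

#' Amplification of a sensitivity parameter
#'
#' Decomposes a single sensitivity parameter `Gamma` into pairs
#' `(Lambda, Delta)` satisfying `Gamma = (Lambda * Delta + 1) /
#' (Lambda + Delta)`, where `Lambda` multiplies the odds of treatment and
#' `Delta` the odds of a positive outcome difference attributable to an
#' unobserved covariate. For each supplied `lambda > gamma`,
#' `delta = (lambda * gamma - 1) / (lambda - gamma)`; values of
#' `lambda <= gamma` admit no finite `delta` and are skipped.
#'
#' @param gamma Sensitivity parameter, must exceed 1.
#' @param lambdas Grid of `Lambda` values.
#' @return data.table with columns `lambda`, `delta` and the recomposed
#'   `gamma_check` (round-trip identity to 1e-9).
#' @export
amplify <- function(gamma, lambdas) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1)
    qm_param_error("amplification requires gamma > 1")
  lambdas <- lambdas[lambdas > gamma]
  delta <- (lambdas * gamma - 1) / (lambdas - gamma)
  data.table(lambda = lambdas, delta = delta,
             gamma_check = (lambdas * delta + 1) / (lambdas + delta))
}
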