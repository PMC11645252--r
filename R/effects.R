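#' Paired 2x2 contingency counts
#'
#' Constructor for the four outcome combinations across matched pairs:
#' `n11` both focals purchased, `n10` only the treated-dyad focal,
#' `n01` only the control-dyad focal, `n00` neither.
#'
#' @param n11,n10,n01,n00 Non-negative integer counts.
#' @return An object of class `qm_counts`.
#' @export
contingency_counts <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(counts < 0) || anyNA(counts))
    qm_param_error("contingency counts must be non-negative")
  n <- sum(counts)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n,
                 shares = if (n > 0) counts / n else counts * NA_real_,
                 empty = n == 0),
            class = "qm_counts")
}

#' Tabulate matched pairs into paired contingency counts
#'
#' @param pairs Matched pairs from [match_pairs()] (or the randomized
#'   variant); needs logical columns `treated_focal_bought`,
#'   `control_focal_bought`.
#' @return A `qm_counts` object; an all-zero table (flagged `empty`) on
#'   empty input.
#' @export
tabulate_pairs <- function(pairs) {
  p <- as.data.table(pairs)
  if (nrow(p) == 0L) return(contingency_counts(0L, 0L, 0L, 0L))
  t <- p$treated_focal_bought
  c <- p$control_focal_bought
  contingency_counts(sum(t & c), sum(t & !c), sum(!t & c), sum(!t & !c))
}

#' @export
print.qm_counts <- function(x, ...) {
  cat(sprintf(
    "paired 2x2 counts (n = %d)\n  both bought      n11 = %d\n  treated only     n10 = %d\n  control only     n01 = %d\n  neither          n00 = %d\n",
    x$n, x$n11, x$n10, x$n01, x$n00))
  invisible(x)
}

rd_rr_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  rd <- (n10 - n01) / n
  rr <- if ((n11 + n01) > 0) (n11 + n10) / (n11 + n01) else NA_real_
  c(rd = rd, rr = rr)
}

#' Paired risk difference and risk ratio with bootstrap CIs
#'
#' Across matched pairs, the risk difference is the focal purchase
#' probability in treated dyads minus that in control dyads,
#' `RD = (n10 - n01)/n`, and the risk ratio is
#' `RR = (n11 + n10)/(n11 + n01)`. Confidence intervals are percentile
#' bootstrap over matched pairs: resampling n pairs with replacement is
#' realized as a multinomial redraw of the four cell counts, which is
#' exactly equivalent because the cell label is the only pair-level datum.
#'
#' @param counts A `qm_counts` object (or matched pairs, tabulated first).
#' @param boot_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `qm_effect`: `rd`, `rr`, `ci_rd`, `ci_rr`,
#'   `n_pairs`, shares and the discordant ratio `n10/n01`. `rr` is `NA`
#'   when no control-side purchases exist.
#' @export
estimate_effect <- function(counts, boot_reps = 1000, seed = 1L,
                            conf = 0.95) {
  if (is.data.frame(counts)) counts <- tabulate_pairs(counts)
  stopifnot(inherits(counts, "qm_counts"))
  if (counts$n == 0L) qm_param_error("cannot estimate from an empty table")
  pt <- rd_rr_from_counts(counts$n11, counts$n10, counts$n01, counts$n00)
  ci <- with_seed(seed, {
    draws <- rmultinom(boot_reps, counts$n,
                       c(counts$n11, counts$n10, counts$n01, counts$n00))
    rds <- (draws[2, ] - draws[3, ]) / counts$n
    rrs <- ifelse(draws[1, ] + draws[3, ] > 0,
                  (draws[1, ] + draws[2, ]) / (draws[1, ] + draws[3, ]),
                  NA_real_)
    a <- (1 - conf) / 2
    list(rd = unname(quantile(rds, c(a, 1 - a))),
         rr = if (all(is.na(rrs))) c(NA_real_, NA_real_)
              else unname(quantile(rrs, c(a, 1 - a), na.rm = TRUE)))
  })
  structure(list(
    rd = unname(pt["rd"]), rr = unname(pt["rr"]),
    ci_rd = ci$rd, ci_rr = ci$rr, n_pairs = counts$n,
    treated_share = (counts$n11 + counts$n10) / counts$n,
    control_share = (counts$n11 + counts$n01) / counts$n,
    discordant_ratio = if (counts$n01 > 0) counts$n10 / counts$n01
                       else NA_real_,
    counts = counts, conf = conf, boot_reps = boot_reps),
    class = "qm_effect")
}

#' @export
print.qm_effect <- function(x, ...) {
  cat(sprintf(
    "RD = %.4f [%.4f, %.4f]   RR = %.3f [%.3f, %.3f]   (n = %d pairs)\n",
    x$rd, x$ci_rd[1], x$ci_rd[2], x$rr, x$ci_rr[1], x$ci_rr[2], x$n_pairs))
  invisible(x)
}

#' Paired chi-squared (McNemar) test of no treatment effect
#'
#' Only the discordant pairs carry information: the statistic is
#' `(n10 - n01)^2 / (n10 + n01)` on 1 df. The exact binomial variant
#' (two-sided sign test of `n10` successes in `n10 + n01` trials at
#' p = 1/2) is also returned.
#'
#' @param counts A `qm_counts` object.
#' @return List with `statistic`, `p_value`, `p_exact`, `n_discordant`.
#'   With no discordant pairs the statistic is `NA` (undefined).
#' @export
paired_chi2 <- function(counts) {
  stopifnot(inherits(counts, "qm_counts"))
  m <- counts$n10 + counts$n01
  if (m == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                p_exact = NA_real_, n_discordant = 0L))
  stat <- (counts$n10 - counts$n01)^2 / m
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       p_exact = binom.test(counts$n10, m, 0.5)$p.value,
       n_discordant = m)
}

# Age in whole years at a transaction time, from birth year only
# (counted from Jan 1 of the birth year).
age_at <- function(when, birth_year) {
  floor(as.numeric(as.Date(when) -
                   as.Date(paste0(birth_year, "-01-01"))) / 365.25)
}

age_tercile <- function(age) {
  cut(age, breaks = c(-Inf, 22, 32, Inf),
      labels = c("<=22", "23-32", ">32"), right = TRUE)
}

#' Subgroup effect estimates over matched pairs
#'
#' Splits the matched pairs by a demographic axis and re-estimates RD/RR
#' per level. Partner attributes are constant within a pair by
#' construction. For focal axes the treated and control focal persons must
#' agree on the attribute; pairs where they differ are dropped and their
#' number reported. Age is computed at the treated dyad's date and binned
#' into terciles (up to 22, 23-32, over 32 years). Users missing from the
#' demographics table form an `"unknown"` level.
#'
#' @param pairs Matched pairs.
#' @param demographics Table from [read_demographics()].
#' @param axis One of `partner_status`, `focal_status`,
#'   `dyad_status_combo`, `partner_gender`, `focal_gender`,
#'   `partner_age_tercile`, `focal_age_tercile`.
#' @param boot_reps,seed Passed to [estimate_effect()].
#' @param min_pairs Levels with fewer pairs are flagged `low_n`
#'   (default 30).
#' @return data.table with one row per level: level, n_pairs, rd, rr, CI
#'   bounds, `low_n` flag; attribute `n_dropped_discordant` for focal
#'   axes.
#' @export
subgroup_estimates <- function(pairs, demographics, axis,
                               boot_reps = 1000, seed = 1L, min_pairs = 30) {
  axes <- c("partner_status", "focal_status", "dyad_status_combo",
            "partner_gender", "focal_gender", "partner_age_tercile",
            "focal_age_tercile")
  if (!axis %in% axes)
    qm_param_error(paste0("unknown axis: ", axis))
  p <- copy(as.data.table(pairs))
  demo <- as.data.table(demographics)
  look <- function(users, field) {
    i <- match(users, demo$user_id)
    v <- demo[[field]][i]
    if (is.numeric(v)) v else fifelse(is.na(v), "unknown", as.character(v))
  }
  dropped <- 0L
  if (axis %in% c("partner_status", "partner_gender")) {
    f <- sub("partner_", "", axis)
    p[, level := look(partner_user, f)]
  } else if (axis == "partner_age_tercile") {
    by_ <- look(p$partner_user, "birth_year")
    p[, level := fifelse(is.na(by_), "unknown",
                         as.character(age_tercile(age_at(treated_date, by_))))]
  } else if (axis %in% c("focal_status", "focal_gender")) {
    f <- sub("focal_", "", axis)
    a <- look(p$treated_focal_user, f)
    b <- look(p$control_focal_user, f)
    keep <- a == b
    dropped <- sum(!keep)
    p <- p[keep]
    p[, level := a[keep]]
  } else if (axis == "focal_age_tercile") {
    ya <- look(p$treated_focal_user, "birth_year")
    yb <- look(p$control_focal_user, "birth_year")
    la <- fifelse(is.na(ya), "unknown",
                  as.character(age_tercile(age_at(p$treated_date, ya))))
    lb <- fifelse(is.na(yb), "unknown",
                  as.character(age_tercile(age_at(p$control_date, yb))))
    keep <- la == lb
    dropped <- sum(!keep)
    p <- p[keep]
    p[, level := la[keep]]
  } else { # dyad_status_combo
    ps <- look(p$partner_user, "status")
    fa <- look(p$treated_focal_user, "status")
    fb <- look(p$control_focal_user, "status")
    keep <- fa == fb
    dropped <- sum(!keep)
    p <- p[keep]
    p[, level := paste(ps[keep], fa[keep], sep = "-")]
  }
  out <- rbindlist(lapply(split(p, p$level), function(sub) {
    est <- estimate_effect(tabulate_pairs(sub), boot_reps = boot_reps,
                           seed = stage_seed(seed, sub$level[1]))
    data.table(level = sub$level[1], n_pairs = est$n_pairs,
               rd = est$rd, rr = est$rr,
               rd_lo = est$ci_rd[1], rd_hi = est$ci_rd[2],
               rr_lo = est$ci_rr[1], rr_hi = est$ci_rr[2],
               low_n = est$n_pairs < min_pairs)
  }))
  setattr(out, "n_dropped_discordant", dropped)
  out[]
}
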