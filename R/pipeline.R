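#' End-to-end analysis of a transaction log
#'
#' Runs the full matched-dyad analysis on an in-memory log: annotation,
#' dyad extraction, the frequent-pair filter, the popularity index,
#' per-item matching, pooled tabulation and effect estimation, the paired
#' chi-squared test and covariate balance. Returns all intermediate
#' counts (the filter funnel) for reporting.
#'
#' @param log Transactions table.
#' @param catalog A `qm_catalog`.
#' @param items Focus items to analyse (data.table `label`/`period`);
#'   defaults to the 13 addition analyses.
#' @param window_seconds,min_joint Dyad extraction and frequency-filter
#'   parameters.
#' @param caliper,caliper_mode,exact_anchor,pop_loo Matching parameters
#'   (see [match_pairs()]).
#' @param boot_reps,seed Estimation parameters.
#' @return List: `funnel`, `pairs`, `per_item`, `pooled_counts`,
#'   `pooled_estimate`, `chi2`, `balance`, `dyads` (the frequent dyads),
#'   `pop` (popularity index), `log` (annotated).
#' @export
analyze_log <- function(log, catalog, items = focus_items(FALSE),
                        window_seconds = 300, min_joint = 10,
                        caliper = 0.10, caliper_mode = "relative",
                        exact_anchor = FALSE, pop_loo = TRUE,
                        boot_reps = 1000, seed = 1L) {
  log <- annotate_transactions(log, catalog)
  dyads <- extract_dyads(log, catalog, window_seconds = window_seconds)
  freq <- filter_frequent_pairs(dyads, min_joint = min_joint)
  pop <- build_popularity_index(log, catalog,
                                labels = unique(items$label))
  pairs <- match_all_items(freq, items, pop, catalog, caliper = caliper,
                           caliper_mode = caliper_mode,
                           exact_anchor = exact_anchor, pop_loo = pop_loo,
                           seed = stage_seed(seed, "match"))
  counts <- tabulate_pairs(pairs)
  est <- if (counts$n > 0)
    estimate_effect(counts, boot_reps = boot_reps,
                    seed = stage_seed(seed, "boot"))
  else NULL
  per_item <- rbindlist(lapply(seq_len(nrow(items)), function(i) {
    sub <- pairs[item == items$label[i] & period == items$period[i]]
    ct <- tabulate_pairs(sub)
    if (ct$n == 0L)
      return(data.table(item = items$label[i], period = items$period[i],
                        n_pairs = 0L, rd = NA_real_, rr = NA_real_,
                        rd_lo = NA_real_, rd_hi = NA_real_,
                        rr_lo = NA_real_, rr_hi = NA_real_))
    e <- estimate_effect(ct, boot_reps = boot_reps,
                         seed = stage_seed(seed, paste0("boot_", i)))
    data.table(item = items$label[i], period = items$period[i],
               n_pairs = e$n_pairs, rd = e$rd, rr = e$rr,
               rd_lo = e$ci_rd[1], rd_hi = e$ci_rd[2],
               rr_lo = e$ci_rr[1], rr_hi = e$ci_rr[2])
  }))
  bal <- if (counts$n >= 2) balance(pairs) else NULL
  elig <- attr(pairs, "eligible")
  list(funnel = c(transactions = nrow(log), dyads = nrow(dyads),
                  frequent_dyads = nrow(freq),
                  eligible_dyads = if (is.null(elig)) 0L
                                   else uniqueN(elig$dyad),
                  matched_pairs = counts$n),
       pairs = pairs, per_item = per_item, pooled_counts = counts,
       pooled_estimate = est,
       chi2 = if (counts$n > 0) paired_chi2(counts) else NULL,
       balance = bal, dyads = freq, pop = pop, log = log)
}

#' Naive unmatched co-purchase contrast
#'
#' The confounded estimator the matched design exists to replace: over
#' all dyads (no matching), the focal purchase share when the partner
#' bought the item minus the share when they did not, averaged over
#' items weighted by the number of partner purchases. Under shared-context
#' confounding or homophily this is biased away from zero even with no
#' mimicry.
#'
#' @param dyads Dyads table.
#' @param catalog A `qm_catalog`.
#' @param items Focus items (defaults to the 13 addition analyses).
#' @return Numeric scalar.
#' @export
naive_contrast <- function(dyads, catalog, items = focus_items(FALSE)) {
  d <- as.data.table(dyads)
  per <- vapply(seq_len(nrow(items)), function(i) {
    sub <- d[period == items$period[i]]
    if (nrow(sub) == 0L) return(c(NA_real_, 0))
    codes <- focus_codes(catalog, items$label[i])
    tr <- txn_contains(sub$partner_items, codes)
    fo <- txn_contains(sub$focal_items, codes)
    if (!any(tr) || all(tr)) return(c(NA_real_, 0))
    c(mean(fo[tr]) - mean(fo[!tr]), sum(tr))
  }, c(0, 0))
  w <- per[2, ]
  ok <- !is.na(per[1, ]) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(per[1, ok] * w[ok]) / sum(w[ok])
}

default_run_config <- function() {
  list(mode = "simulate", sim = list(), log = NULL, catalog = NULL,
       demographics = NULL, items = "additions", window_seconds = 300,
       min_joint = 10, caliper = 0.10, caliper_mode = "relative",
       exact_anchor = FALSE, pop_loo = TRUE, boot_reps = 1000, seed = 1L,
       randomized = TRUE, dose = TRUE, sensitivity = TRUE,
       subgroup_axes = character(), out_dir = NULL)
}

#' Run the full study from one configuration
#'
#' Orchestrates simulate/ingest, dyad extraction, matching, estimation
#' and the robustness analyses, returning a machine-readable report.
#' Every stage's parameters are echoed into the report; all randomness is
#' derived from the master `seed` by stage-name hashing, so two runs with
#' the same configuration are identical.
#'
#' @param config Named list (unknown keys are rejected): `mode`
#'   (`"simulate"` or `"files"`), `sim` (arguments to [sim_config()]),
#'   `log`/`catalog`/`demographics` (file paths for `"files"` mode),
#'   `items` (`"additions"`, `"all"`, or a `label`/`period` data.frame),
#'   `window_seconds`, `min_joint`, `caliper`, `caliper_mode`,
#'   `exact_anchor`, `boot_reps`, `seed`, `randomized`, `dose`,
#'   `sensitivity` (logical stage switches), `subgroup_axes`, `out_dir`.
#'   May also be the path of a YAML file holding that list.
#' @return The report, a nested list (see [write_report()] for the file
#'   layout).
#' @export
run_study <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    qm_config_error(paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  cfg <- modifyList(base, config)
  seed <- as.integer(cfg$seed)

  truth <- NULL; demo <- NULL
  if (cfg$mode == "simulate") {
    sim_args <- cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(seed, "sim")
    sim <- simulate_purchase_log(do.call(sim_config, sim_args))
    log <- sim$log; catalog <- sim$catalog
    truth <- sim$truth; demo <- sim$demographics
  } else if (cfg$mode == "files") {
    catalog <- read_catalog(cfg$catalog)
    log <- read_transactions(cfg$log, catalog, quiet = TRUE)
    if (!is.null(cfg$demographics)) demo <- read_demographics(cfg$demographics)
  } else qm_config_error("mode must be 'simulate' or 'files'")

  items <- if (is.data.frame(cfg$items)) as.data.table(cfg$items)
           else if (identical(cfg$items, "all")) focus_items(TRUE)
           else focus_items(FALSE)

  an <- analyze_log(log, catalog, items = items,
                    window_seconds = cfg$window_seconds,
                    min_joint = cfg$min_joint, caliper = cfg$caliper,
                    caliper_mode = cfg$caliper_mode,
                    exact_anchor = cfg$exact_anchor, pop_loo = cfg$pop_loo,
                    boot_reps = cfg$boot_reps, seed = seed)

  report <- list(
    schema_version = "1.0",
    params = cfg[setdiff(names(cfg), c("sim", "out_dir"))],
    sim_params = if (cfg$mode == "simulate")
      cfg$sim[setdiff(names(cfg$sim), "base_pop")] else NULL,
    funnel = as.list(an$funnel),
    pooled = if (!is.null(an$pooled_estimate)) list(
      counts = unclass(an$pooled_counts)[c("n11", "n10", "n01", "n00", "n")],
      rd = an$pooled_estimate$rd, rr = an$pooled_estimate$rr,
      ci_rd = an$pooled_estimate$ci_rd, ci_rr = an$pooled_estimate$ci_rr,
      chi2 = an$chi2),
    per_item = an$per_item,
    balance = an$balance,
    ground_truth_rd = if (!is.null(truth)) ground_truth_rd(truth) else NULL)

  if (isTRUE(cfg$randomized) && nrow(an$dyads) > 0) {
    rnd <- randomize_partners(an$dyads, an$log, catalog,
                              seed = stage_seed(seed, "randomize"))
    rp <- match_all_items(rnd, items, an$pop, catalog,
                          caliper = cfg$caliper,
                          caliper_mode = cfg$caliper_mode,
                          exact_anchor = cfg$exact_anchor,
                          pop_loo = cfg$pop_loo,
                          seed = stage_seed(seed, "match_rnd"))
    rc <- tabulate_pairs(rp)
    report$randomized <- if (rc$n > 0) {
      e <- estimate_effect(rc, boot_reps = cfg$boot_reps,
                           seed = stage_seed(seed, "boot_rnd"))
      list(n_pairs = rc$n, rd = e$rd, rr = e$rr,
           ci_rd = e$ci_rd, ci_rr = e$ci_rr,
           n_dropped = attr(rnd, "n_dropped"))
    } else list(n_pairs = 0L)
  }

  if (isTRUE(cfg$dose) && an$pooled_counts$n > 0) {
    report$dose_response <- tryCatch({
      dr <- dose_response(an$pairs)
      list(bins = dr$bins, slope_rd = dr$slope_rd, p_rd = dr$p_rd,
           slope_rr = dr$slope_rr, p_rr = dr$p_rr,
           n_overflow = dr$n_overflow)
    }, qmimic_error = function(e) list(error = conditionMessage(e)))
  }

  if (isTRUE(cfg$sensitivity) && an$pooled_counts$n10 + an$pooled_counts$n01 > 0) {
    sens <- rosenbaum_gamma(an$pooled_counts)
    gg <- seq(1, max(1.5, sens$gamma_star * 1.5), length.out = 25)
    amp <- if (is.finite(sens$gamma_star) && sens$gamma_star > 1)
      amplify(sens$gamma_star,
              sens$gamma_star * c(1.2, 1.5, 2, 3, 5, 10))
    else NULL
    report$sensitivity <- list(
      gamma_star = sens$gamma_star, alpha = sens$alpha,
      pbound_curve = data.table(gamma = gg,
                                pbound = vapply(gg, sens$pbound, 0)),
      amplification = amp)
  }

  if (length(cfg$subgroup_axes) && !is.null(demo) && an$pooled_counts$n > 0) {
    report$subgroups <- lapply(setNames(nm = cfg$subgroup_axes), function(ax)
      subgroup_estimates(an$pairs, demo, ax, boot_reps = cfg$boot_reps,
                         seed = stage_seed(seed, paste0("sub_", ax))))
  }

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir, pairs = an$pairs)
  report
}

#' Write a study report to disk
#'
#' Writes `report.json` (the full report), `effects.csv` (per-item
#' estimates) and optionally `pairs.csv`.
#'
#' @param report Output of [run_study()].
#' @param dir Output directory (created if needed).
#' @param pairs Optional matched pairs to export.
#' @export
write_report <- function(report, dir, pairs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (!is.null(report$per_item))
    fwrite(report$per_item, file.path(dir, "effects.csv"))
  if (!is.null(pairs) && nrow(pairs)) {
    p <- copy(as.data.table(pairs))
    setattr(p, "eligible", NULL)
    fwrite(p, file.path(dir, "pairs.csv"))
  }
  invisible(dir)
}
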