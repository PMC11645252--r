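#' Closed vocabulary of item categories
#'
#' Item codes are mapped to one of these categorical labels by the item
#' catalog. `meal` defines the lunch anchor; `coffee` and `tea` define the
#' breakfast/afternoon anchors; the remaining categories are the addition
#' items analysed for mimicry.
#'
#' @return Character vector of valid category labels.
#' @export
item_categories <- function() {
  c("meal", "coffee", "tea", "condiment", "salad", "pastry", "dessert",
    "soup", "soft_drink", "fruit", "other")
}

#' Meal-period boundaries
#'
#' Half-open daily windows: breakfast 06:00-11:00, lunch 11:00-14:30,
#' afternoon 14:30-20:00. Transactions outside 06:00-20:00 belong to no
#' period and are excluded from dyad analysis.
#'
#' @return Named list of `c(start, end)` second-of-day pairs.
#' @export
meal_periods <- function() {
  list(breakfast = c(6 * 3600, 11 * 3600),
       lunch     = c(11 * 3600, 14.5 * 3600),
       afternoon = c(14.5 * 3600, 20 * 3600))
}

#' Build an item catalog
#'
#' @param df Data frame with columns `item_code`, `category`,
#'   `vegetarian_flag` (`"yes"`, `"no"` or `"na"`; only meaningful for
#'   meal-category items).
#' @return A `qm_catalog` data.table.
#' @export
as_catalog <- function(df) {
  need <- c("item_code", "category", "vegetarian_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    qm_schema_error(paste0("catalog is missing column(s): ",
                           paste(miss, collapse = ", ")))
  cat <- as.data.table(df)[, .(item_code = as.character(item_code),
                               category = as.character(category),
                               vegetarian_flag = as.character(vegetarian_flag))]
  bad <- setdiff(unique(cat$category), item_categories())
  if (length(bad))
    qm_taxonomy_error(paste0("unknown item category: ",
                             paste(bad, collapse = ", ")))
  if (anyDuplicated(cat$item_code))
    qm_schema_error("duplicate item_code in catalog")
  bad_flag <- setdiff(unique(cat$vegetarian_flag), c("yes", "no", "na"))
  if (length(bad_flag))
    qm_schema_error(paste0("vegetarian_flag must be yes/no/na, got: ",
                           paste(bad_flag, collapse = ", ")))
  setattr(cat, "class", c("qm_catalog", class(cat)))
  cat[]
}

#' Read an item catalog from CSV
#'
#' Expected header: `item_code,category,vegetarian_flag`.
#'
#' @param path Path to the CSV file.
#' @return A `qm_catalog` data.table.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) qm_schema_error(paste0("no such file: ", path))
  as_catalog(fread(path, colClasses = "character"))
}

# Codes belonging to a category (internal).
codes_of_category <- function(catalog, category) {
  catalog$item_code[catalog$category == category]
}

# Resolve item codes against the catalog; unknown codes are a hard error.
check_codes <- function(codes, catalog) {
  unknown <- setdiff(unique(codes), catalog$item_code)
  if (length(unknown))
    qm_taxonomy_error(paste0("item code(s) not in catalog: ",
                             paste(sort(unknown), collapse = ", ")))
  invisible(TRUE)
}

#' Read a transaction log from CSV
#'
#' Dialect: comma-separated with header
#' `txn_id,user_id,shop_id,register_id,timestamp,items`, ISO-8601
#' timestamps, and the `items` cell holding `;`-separated item codes.
#' Every code must resolve in the catalog. The result is sorted by
#' (shop, register, timestamp, txn_id), the order dyad extraction expects.
#'
#' @param path Path to the CSV log.
#' @param catalog A `qm_catalog` used to validate item codes.
#' @param quiet Suppress the row-count message.
#' @return A data.table of transactions.
#' @export
read_transactions <- function(path, catalog, quiet = FALSE) {
  if (!file.exists(path)) qm_schema_error(paste0("no such file: ", path))
  need <- c("txn_id", "user_id", "shop_id", "register_id", "timestamp", "items")
  log <- fread(path, colClasses = "character")
  miss <- setdiff(need, names(log))
  if (length(miss))
    qm_schema_error(paste0("transaction log is missing column(s): ",
                           paste(miss, collapse = ", ")))
  log <- log[, need, with = FALSE]
  ts <- as.POSIXct(log$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) qm_schema_error("unparseable timestamp(s) in transaction log")
  log[, timestamp := ts]
  if (any(!nzchar(log$items)))
    qm_schema_error("transaction with empty items set")
  if (anyDuplicated(log$txn_id)) qm_schema_error("duplicate txn_id")
  check_codes(unlist(split_items(log$items)), catalog)
  setorder(log, shop_id, register_id, timestamp, txn_id)
  if (!quiet) message(sprintf("read %d transactions from %s", nrow(log), path))
  log[]
}

#' Write a transaction log to CSV
#'
#' Inverse of [read_transactions()]: same dialect, so a write-read
#' round-trip reproduces the record set.
#'
#' @param log Transactions data.table.
#' @param path Output path.
#' @export
write_transactions <- function(log, path) {
  out <- as.data.table(log)[, .(txn_id, user_id, shop_id, register_id,
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), items)]
  fwrite(out, path)
  invisible(path)
}

#' Read a user demographics table from CSV
#'
#' Expected header: `user_id,status,gender,birth_year`. Status is one of
#' `student`, `staff`, `other`; users absent from the table are treated as
#' `unknown` by subgroup analyses, never imputed.
#'
#' @param path Path to the CSV file.
#' @return A data.table keyed by `user_id`.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) qm_schema_error(paste0("no such file: ", path))
  need <- c("user_id", "status", "gender", "birth_year")
  d <- fread(path)
  miss <- setdiff(need, names(d))
  if (length(miss))
    qm_schema_error(paste0("demographics is missing column(s): ",
                           paste(miss, collapse = ", ")))
  d <- d[, .(user_id = as.character(user_id), status = as.character(status),
             gender = as.character(gender),
             birth_year = as.integer(birth_year))]
  bad <- setdiff(unique(d$status), c("student", "staff", "other"))
  if (length(bad))
    qm_schema_error(paste0("status must be student/staff/other, got: ",
                           paste(bad, collapse = ", ")))
  d[]
}

#' Assign meal periods to timestamps
#'
#' Deterministic mapping of a clock time to breakfast / lunch / afternoon
#' using the half-open boundaries of [meal_periods()]. Times outside
#' 06:00-20:00 map to `NA` and are dropped downstream.
#'
#' @param timestamp POSIXct vector (or a transactions table with a
#'   `timestamp` column).
#' @return Character vector of period labels (`NA` outside service hours).
#' @export
assign_period <- function(timestamp) {
  if (is.data.frame(timestamp)) timestamp <- timestamp$timestamp
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  sec <- lt$hour * 3600 + lt$min * 60 + lt$sec
  out <- rep(NA_character_, length(sec))
  for (p in names(meal_periods())) {
    b <- meal_periods()[[p]]
    out[sec >= b[1] & sec < b[2]] <- p
  }
  out
}

#' Anchor purchase of a transaction
#'
#' The anchor is the period-defining purchase: a meal-category item during
#' lunch, or a beverage (coffee or tea) during breakfast and afternoon.
#' A transaction containing both coffee and tea is labelled `"coffee"`
#' (the dominant beverage; a deterministic tie-break is required).
#' Transactions without the period-appropriate anchor return `NA` and
#' cannot join a dyad, though they still occupy a queue slot.
#'
#' @param items Character vector of `;`-joined item codes.
#' @param period Character vector of period labels (recycled if length 1).
#' @param catalog A `qm_catalog`.
#' @param refined If `TRUE`, split the meal anchor into
#'   `"meal_veg"`/`"meal_std"` using the catalog's vegetarian flag
#'   (used by exact-anchor matching and the anchor-type analyses).
#' @return Character vector of anchor labels, `NA` where no anchor.
#' @export
anchor_of <- function(items, period, catalog, refined = FALSE) {
  if (length(period) == 1L) period <- rep(period, length(items))
  stopifnot(length(period) == length(items))
  meal_codes   <- codes_of_category(catalog, "meal")
  veg_codes    <- catalog$item_code[catalog$category == "meal" &
                                    catalog$vegetarian_flag == "yes"]
  coffee_codes <- codes_of_category(catalog, "coffee")
  tea_codes    <- codes_of_category(catalog, "tea")
  out <- rep(NA_character_, length(items))
  lunch <- !is.na(period) & period == "lunch"
  bev   <- !is.na(period) & period %in% c("breakfast", "afternoon")
  has_meal <- txn_contains(items, meal_codes)
  out[lunch & has_meal] <- "meal"
  if (refined) {
    has_veg <- txn_contains(items, veg_codes)
    out[lunch & has_meal & has_veg]  <- "meal_veg"
    out[lunch & has_meal & !has_veg] <- "meal_std"
  }
  has_cof <- txn_contains(items, coffee_codes)
  has_tea <- txn_contains(items, tea_codes)
  out[bev & has_tea] <- "tea"
  out[bev & has_cof] <- "coffee"   # coffee wins when both present
  out
}

#' Annotate a transaction log with date, period and anchors
#'
#' Adds `date`, `period`, `anchor` and `anchor_refined` columns used by
#' dyad extraction and matching. Idempotent.
#'
#' @param log Transactions data.table.
#' @param catalog A `qm_catalog`.
#' @return The annotated data.table (a copy).
#' @export
annotate_transactions <- function(log, catalog) {
  log <- as.data.table(log)
  log <- copy(log)
  log[, date := as.Date(timestamp, tz = "UTC")]
  log[, period := assign_period(timestamp)]
  log[, anchor := anchor_of(items, period, catalog)]
  log[, anchor_refined := anchor_of(items, period, catalog, refined = TRUE)]
  log[]
}
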