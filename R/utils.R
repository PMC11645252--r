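# Internal helpers shared across modules.

# Classed error constructors so callers/tests can distinguish failure modes.
qm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qmimic_error")))
}

qm_schema_error   <- function(msg) qm_stop(msg, "qmimic_schema_error")
qm_taxonomy_error <- function(msg) qm_stop(msg, "qmimic_taxonomy_error")
qm_order_error    <- function(msg) qm_stop(msg, "qmimic_order_error")
qm_param_error    <- function(msg) qm_stop(msg, "qmimic_param_error")
qm_config_error   <- function(msg) qm_stop(msg, "qmimic_config_error")

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic package functions
# route their seeds through this.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific 31-bit seed from a master seed and a stage name,
# so pipeline stages draw from independent streams.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L + 1)
}

# escape every non-word character so arbitrary item codes are regex-safe
escape_regex <- function(x) gsub("([^A-Za-z0-9_])", "\\\\\\1", x)

# Does each ';'-delimited item string contain at least one of `codes`?
txn_contains <- function(items, codes) {
  if (length(codes) == 0L) return(rep(FALSE, length(items)))
  pat <- paste0("(^|;)(", paste(escape_regex(codes), collapse = "|"), ")(;|$)")
  grepl(pat, items)
}

split_items <- function(items) strsplit(items, ";", fixed = TRUE)

join_items <- function(codes) vapply(codes, paste, "", collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a
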