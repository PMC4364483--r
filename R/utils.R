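# Internal helpers: error conditions and seeded RNG scoping.

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("coloc_validation_error", "error", "condition")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("coloc_io_error", "error", "condition")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("coloc_config_error", "error", "condition")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit seed derived from a base seed and one or more labels.
# Labels are sorted first so the derived stream is invariant to role order
# (region set as center vs as track); keeps every derived seed < 2^31.
derive_seed <- function(seed, labels) {
  key <- paste(sort(as.character(labels)), collapse = "\x1f")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647L
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
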