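# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_phenomap <- function(msg, class) {
  stop(structure(
    class = c(class, "phenomap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) abort_phenomap(msg, "phenomap_validation_error")
stop_config <- function(msg) abort_phenomap(msg, "phenomap_config_error")
stop_dimension <- function(msg) abort_phenomap(msg, "phenomap_dimension_error")

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_validation(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic substream seeds below 2^31, spread by a large prime multiplier.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483629 * 7919 + index * 104729) %% 2147483629) + 1L
}

# Truncated-normal draws by inverse-CDF; bounds are respected exactly.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ordered severity levels used throughout: never-smoker controls then GOLD 0-4.
stage_levels <- function() c("control", "GOLD0", "GOLD1", "GOLD2", "GOLD3", "GOLD4")

as_stage <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "1", "2", "3", "4")] <- paste0("GOLD", x[x %in% c("0", "1", "2", "3", "4")])
  if (!all(x %in% stage_levels())) {
    stop_validation(sprintf(
      "invalid stage value(s): %s (expected %s)",
      paste(unique(setdiff(x, stage_levels())), collapse = ", "),
      paste(stage_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = stage_levels(), ordered = TRUE)
}
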