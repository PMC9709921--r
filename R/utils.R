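#' @keywords internal
"_PACKAGE"

# Structured condition helpers: every user-facing failure carries a subclass
# so callers (and the CLI) can dispatch on the kind of error.
ttmd_error <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "ttmd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

config_error    <- function(msg, ...) ttmd_error("ttmd_config_error", msg, ...)
selector_error  <- function(msg, ...) ttmd_error("ttmd_selector_error", msg, ...)
format_error    <- function(msg, ...) ttmd_error("ttmd_format_error", msg, ...)
geometry_error  <- function(msg, ...) ttmd_error("ttmd_geometry_error", msg, ...)
usage_error     <- function(msg, ...) ttmd_error("ttmd_usage_error", msg, ...)
parameter_error <- function(msg, ...) ttmd_error("ttmd_parameter_error", msg, ...)
domain_error    <- function(msg, ...) ttmd_error("ttmd_domain_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps engine runs reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one master seed per replicate, windows
# and replicates get distinct streams. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + as.numeric(index) * 9176) %% 2147483629L)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) geometry_error("cannot normalise a zero vector")
  v / n
}
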