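# internal condition helpers: usage errors (bad arguments / malformed requests)
# map to CLI exit code 2, runtime errors (data-dependent failures) to 1.

.stopUsage <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("scmr_usage_error", "scmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.stopRuntime <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("scmr_runtime_error", "scmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.checkCount <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    .stopUsage("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) .stopUsage("'%s' out of range", name)
  as.numeric(x)
}

# locale-independent lexicographic sort (byte order), so the gene-union
# feature order is identical on every machine
.lexSort <- function(x) sort(x, method = "radix")
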