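# Locale-independent ordering helpers. Node identifiers are opaque,
# case-sensitive strings; every ordering in the package must be byte-stable
# across platforms, so all sorting goes through radix (C-collation) order.

sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Elementwise "a < b" under radix collation (base `<` on character is
# locale-dependent).
str_lt <- function(a, b) {
  u <- sort_c(unique(c(a, b)))
  match(a, u) < match(b, u)
}

# Classed conditions so callers (and the CLI) can react per error kind.
spn_stop <- function(subclass, msg) {
  cond <- structure(
    class = c(paste0("spn_", subclass), "spn_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

# Absolute tolerance for distance ties in weighted mode; unweighted
# comparisons are exact integer arithmetic.
SPN_TOL <- 1e-9

spn_tol <- function(weighted) if (weighted) SPN_TOL else 0
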