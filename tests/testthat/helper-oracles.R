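# Independent Mann-Whitney oracle: U by direct pairwise comparison counting,
# exact two-sided p by enumeration of all group assignments of the pooled
# sample. Deliberately avoids rank sums, the path the implementation uses.
mw_oracle <- function(x, y) {
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  U <- ustat(x, y)
  idx <- utils::combn(n, n1)
  Us <- apply(idx, 2, function(ii) ustat(pooled[ii], pooled[-ii]))
  center <- n1 * (n - n1) / 2
  list(U = U, p = mean(abs(Us - center) >= abs(U - center) - 1e-9))
}

# closed-form weighted least-squares slope
wls_slope_oracle <- function(y, x, w) {
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
}
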