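# Pooled-variance two-sided Student's t with explicit degenerate handling:
# zero pooled variance gives t = 0 / p = 1 for equal means and an infinite
# statistic (p = 0) otherwise.
.pooled_t <- function(a, b) {
  if (stats::var(a) + stats::var(b) > 0) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value)
  } else if (mean(a) == mean(b)) {
    list(t = 0, p = 1)
  } else {
    list(t = sign(mean(a) - mean(b)) * Inf, p = 0)
  }
}
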