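# p-value rendering used throughout the report surfaces: 2 dp, with very
# small values shown as "< 0.01" and non-estimable ones as "NE".
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("NE")
    if (pi < 0.01) return("< 0.01")
    if (pi > 0.99) return("> 0.99")
    sprintf("%.2f", pi)
  }, character(1))
}

format_est_ci <- function(d, lo, hi, digits = 2) {
  sprintf("%.*f [%.*f, %.*f]", digits, d, digits, lo, digits, hi)
}

# deterministic substream seeds below 2^31, so that per-outcome/per-arm
# draws do not perturb one another when a scenario grows
substream_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 69069 + kv * 7919 + 1) %% 2147483647
  }
  as.integer(h)
}
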