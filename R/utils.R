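# shared small helpers

# round-half-up at d decimals (R's round() halves to even, which does not
# match how design tables are conventionally printed)
round_half_up <- function(x, d = 0) {
  s <- 10^d
  out <- floor(x * s + 0.5 + 1e-9) / s
  out[is.na(x)] <- NA_real_
  out
}

cap1 <- function(x) {
  paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))
}
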