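# Independent brute-force encoding of the activity-index table, written as
# a literal if-chain over the published rows (deliberately unrelated to the
# band/table representation used by score_recording).
brute_index <- function(w, bp, cr) {
  echo <- cr > 0
  bpp <- bp > 0
  if (w == 0 && !echo && !bpp) return(0)                 # no signals
  if (w == 0 && bpp && !echo) return(if (bp < 10) 1 else 1.5)
  if (w == 0 && echo && !bpp) return(if (cr < 2) 1 else 1.5)
  if (w == 0 && echo && bpp) return(if (bp < 10) 1.5 else 2.5)
  if (w >= 1 && w <= 20) {
    if (!echo && !bpp) return(1)
    if (echo && bpp) return(3)
    return(2)                                            # echolocation or BP
  }
  if (w >= 21 && w <= 40) {
    if (!echo && !bpp) return(1.5)
    if (echo && bpp) return(3.5)
    return(3)
  }
  if (!echo && !bpp) return(2.5)                         # >= 41 whistles
  if (echo && bpp) return(4)
  3.5
}

# Exhaustive sign-flip enumeration of the two-sided signed-rank p-value
# (null: each difference is +/- with probability 1/2).
signflip_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Tiny helper: segment records at given hour offsets with given indices.
records_at <- function(times, indices, site = "B") {
  data.frame(site_id = site, start = as.POSIXct(times, tz = "UTC"),
             duration_s = 180, index = indices)
}
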