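# Random cascade parameter sets spanning ~3 orders of magnitude in pools
# and flux. Uses the session RNG; callers set the seed.
rand_cascade_params <- function(n, min_gap = 0) {
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    pools <- 10^runif(3, -1.5, 1.5)
    if (min_gap > 0 &&
        mepflux:::min_pool_gap(pools[1], pools[2], pools[3]) < min_gap) {
      next
    }
    out[[i]] <- cascade_params(pools[1], pools[2], pools[3],
                               flux = 10^runif(1, -1.5, 1.5),
                               plateau = runif(1, 0.05, 1))
    i <- i + 1L
  }
  out
}

# Partial-fraction coefficients of the closed form, for identity checks.
cascade_coefs <- function(p) {
  A <- p$pool_dxp; B <- p$pool_mecdp; C <- p$pool_idpdmadp
  c(A^2 / ((A - B) * (A - C)),
    B^2 / ((B - A) * (B - C)),
    C^2 / ((C - A) * (C - B)))
}
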