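# Independent brute-force metric oracles (naive loops, no vectorized reuse of
# the package's own code paths).

loop_nrmse <- function(pred, gt) {
  num <- 0; den <- 0
  for (i in seq_along(gt)) {
    num <- num + (pred[i] - gt[i])^2
    den <- den + gt[i]^2
  }
  sqrt(num / den)
}

loop_r2 <- function(pred, gt, inside) {
  gk <- gt[inside]
  mu <- mean(gk)
  num <- 0; den <- 0
  for (k in inside) {
    num <- num + (gt[k] - pred[k])^2
    den <- den + (gt[k] - mu)^2
  }
  1 - num / den
}

loop_cog <- function(vol, inside, d) {
  s <- c(0, 0, 0); tot <- 0
  for (k in inside) {
    xyz <- arrayInd(k, d) - 1
    s <- s + vol[k] * xyz
    tot <- tot + vol[k]
  }
  as.numeric(s / tot)
}
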