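## Independent brute-force RAD oracle: same accepted-set blocking semantics
## as the frozen criterion, but written as a direct minimum-image double loop
## with no sorting shortcuts or pre-cut.
brute_rad <- function(com, center, box) {
  others <- setdiff(seq_len(nrow(com)), center)
  disp <- t(vapply(others, function(j) {
    d <- com[j, ] - com[center, ]
    d - round(d / box) * box
  }, numeric(3)))
  r <- sqrt(rowSums(disp^2))
  shell <- integer(0)
  for (j in others[order(r, others)]) {
    jj <- match(j, others)
    blocked <- FALSE
    for (k in shell) {
      kk <- match(k, others)
      cosang <- sum(disp[jj, ] * disp[kk, ]) / (r[jj] * r[kk])
      if (1 / r[jj]^2 < cosang / r[kk]^2) blocked <- TRUE
    }
    if (!blocked) shell <- c(shell, j)
  }
  sort(shell)
}
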