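# Brute-force direct-summation Patterson at the same grid points as the
# FFT synthesis: the independent oracle for the transform. Quadratic cost,
# only usable on small reflection sets.
directPatterson <- function(set, dims) {
  hkl <- cbind(set@data$h, set@data$k, set@data$l)
  I <- set@data$I
  H <- rbind(hkl, -hkl); I2 <- c(I, I)
  keep <- !duplicated((H[, 1] + 1024) * 2048^2 + (H[, 2] + 1024) * 2048 +
                        (H[, 3] + 1024))
  H <- H[keep, , drop = FALSE]; I2 <- I2[keep]
  P <- array(0, dims)
  kk <- (seq_len(dims[3]) - 1) / dims[3]
  for (a in seq_len(dims[1])) for (b in seq_len(dims[2])) {
    u <- cbind((a - 1) / dims[1], (b - 1) / dims[2], kk)
    P[a, b, ] <- colSums(I2 * cos(2 * pi * (H %*% t(u))))
  }
  P * 100 / P[1, 1, 1]
}
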