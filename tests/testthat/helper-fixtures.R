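# shared, cheap-to-build objects reused across test files
tg <- toy_generator(seed = 3)
pb_rc <- randconv_backend()
pb_px <- pixel_backend()

rand_img <- function(side = 16, seed = 1, range = "unit") {
  set.seed(seed)
  lim <- if (range == "unit") 1 else 255
  image_grid(array(runif(side * side * 3, 0, lim), c(side, side, 3)),
             range = range, colorspace = "RGB")
}

# brute-force double-loop autocorrelation regularizer (independent oracle)
brute_noise_reg <- function(maps) {
  tot <- 0
  for (n in maps) {
    m <- n
    repeat {
      r <- nrow(m)
      ah <- 0; av <- 0
      for (x in 2:r) for (y in 1:r) ah <- ah + m[x, y] * m[x - 1, y]
      for (x in 1:r) for (y in 2:r) av <- av + m[x, y] * m[x, y - 1]
      tot <- tot + (ah / r^2)^2 + (av / r^2)^2
      if (r <= 8) break
      m2 <- matrix(0, r / 2, r / 2)
      for (i in seq_len(r / 2)) for (j in seq_len(r / 2))
        m2[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
      m <- m2
    }
  }
  tot
}

# brute-force 3x3 in-bounds minimum filter (independent oracle)
brute_erode <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- px
  for (k in seq_len(dim(px)[3]))
    for (i in seq_len(H)) for (j in seq_len(W)) {
      rs <- max(1, i - 1):min(H, i + 1)
      cs <- max(1, j - 1):min(W, j + 1)
      out[i, j, k] <- min(px[rs, cs, k])
    }
  out
}
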