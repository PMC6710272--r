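# fixture builders shared across test files; everything is generated in
# code so the suite carries no binary data

# binary disk mask centered in a square image
make_disk <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cx <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2) * 1
}

make_ellipse <- function(a, b, pad = 10) {
  n <- 2 * a + 2 * pad + 1
  cx <- a + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - cx) / a)^2 + ((j - cx) / b)^2 <= 1) * 1
}

make_square <- function(s, pad = 10) {
  n <- s + 2 * pad
  m <- matrix(0, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- 1
  m
}

make_star <- function(r0, amp, k = 4, pad = 12) {
  n <- ceiling(2 * r0 * (1 + amp)) + 2 * pad + 1
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    th <- atan2(j - cx, i - cx)
    sqrt((i - cx)^2 + (j - cx)^2) <= r0 * (1 + amp * sin(k * th))
  }) * 1
}

# random named count matrix
make_counts <- function(genes, spheroids, lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(genes * spheroids, lambda), genes, spheroids,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("s%02d", seq_len(spheroids))))
  storage.mode(m) <- "integer"
  m
}

# image spec with n_round disks (area > 300) and n_debris sub-300-px specks
make_image_spec <- function(n_round = 3, n_debris = 5, shape = c(220, 220),
                            noise_sd = 2, seed = 1, channels = "mask") {
  set.seed(seed)
  centers <- list(c(55, 55), c(55, 165), c(165, 55), c(165, 165))
  objects <- list()
  for (i in seq_len(n_round))
    objects[[i]] <- list(center = centers[[i]], radius = 22 + 2 * i,
                         intensity = 150, class = "round")
  for (i in seq_len(n_debris)) {
    objects[[n_round + i]] <- list(
      center = c(15 + 12 * i, 200), radius = 3, intensity = 150,
      class = "debris")
  }
  synthetic_image_spec(shape, objects, noise_sd = noise_sd,
                       channels = channels)
}
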