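# Independent oracles and fixture builders used across the suite.

# Brute-force discretized Gauss double sum, written as explicit loops in
# plain R: the reference implementation against which the package's
# vectorized and prefix-sum paths are checked.
bruteGauss <- function(xyz, a, b) {
  n <- nrow(xyz)
  mid <- (xyz[-n, , drop = FALSE] + xyz[-1, , drop = FALSE]) / 2
  dR <- diff(xyz)
  tot <- 0
  for (i in a[1]:(a[2] - 1)) {
    for (j in b[1]:(b[2] - 1)) {
      r <- mid[i, ] - mid[j, ]
      cr <- c(dR[i, 2] * dR[j, 3] - dR[i, 3] * dR[j, 2],
              dR[i, 3] * dR[j, 1] - dR[i, 1] * dR[j, 3],
              dR[i, 1] * dR[j, 2] - dR[i, 2] * dR[j, 1])
      tot <- tot + sum(r * cr) / sum(r^2)^1.5
    }
  }
  tot / (4 * pi)
}

# plain-R Gauss kernel matrix (bond-pair contributions), independent of
# the compiled implementation
bruteKernel <- function(xyz) {
  n <- nrow(xyz)
  mid <- (xyz[-n, , drop = FALSE] + xyz[-1, , drop = FALSE]) / 2
  dR <- diff(xyz)
  nb <- n - 1L
  K <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i == j) next
    r <- mid[i, ] - mid[j, ]
    cr <- c(dR[i, 2] * dR[j, 3] - dR[i, 3] * dR[j, 2],
            dR[i, 3] * dR[j, 1] - dR[i, 1] * dR[j, 3],
            dR[i, 1] * dR[j, 2] - dR[i, 2] * dR[j, 1])
    K[i, j] <- sum(r * cr) / sum(r^2)^1.5 / (4 * pi)
  }
  K
}

randomTrace <- function(n, seed, sd = 5) {
  set.seed(seed)
  ChainTrace(matrix(rnorm(3 * n, sd = sd), n, 3),
             id = paste0("rand", seed))
}

# random rigid motion (proper rotation + translation)
rigidMotion <- function(xyz, seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr <- qr(M)
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(xyz)) + matrix(rnorm(3, sd = 20), nrow(xyz), 3, byrow = TRUE)
}

# synthetic loop record table
randomLoopTable <- function(m, seed, id = "p1") {
  set.seed(seed)
  i1 <- sample(1:200, m, replace = TRUE)
  i2 <- i1 + sample(10:60, m, replace = TRUE)
  j1 <- i2 + sample(1:40, m, replace = TRUE)
  data.frame(id = id, i1 = i1, i2 = i2, j1 = j1,
             j2 = j1 + sample(10:50, m, replace = TRUE),
             g = runif(m, 1, 3) * sample(c(-1, 1), m, replace = TRUE),
             stringsAsFactors = FALSE)
}

writeFixturePDB <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

caLine <- function(serial, resname, resno, x, y, z, alt = " ") {
  sprintf("ATOM  %5d  CA %s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, alt, resname, resno, x, y, z)
}
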