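# Shared fixtures and independent oracles.  Everything is generated in
# code; oracles deliberately use brute-force formulations independent of
# the implementation paths they check.

# a filled uniform disk, value 1 inside radius r (pixel units from center)
diskImage <- function(n, r = n / 3) {
  c0 <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n) - c0
  y <- c0 - matrix(rep(0:(n - 1), times = n), n)
  ImageGrid((x^2 + y^2 <= r^2) * 1)
}

# independent Shepp-Logan oracle: hand-coded ellipse membership test,
# standard modified-contrast table
oracleEllipseSum <- function(x, y) {
  E <- list(
    c(1, .69, .92, 0, 0, 0),
    c(-0.8, .6624, .8740, 0, -.0184, 0),
    c(-0.2, .1100, .3100, .22, 0, -18),
    c(-0.2, .1600, .4100, -.22, 0, 18),
    c(0.1, .2100, .2500, 0, .35, 0),
    c(0.1, .0460, .0460, 0, .1, 0),
    c(0.1, .0460, .0460, 0, -.1, 0),
    c(0.1, .0460, .0230, -.08, -.605, 0),
    c(0.1, .0230, .0230, 0, -.605, 0),
    c(0.1, .0230, .0460, .06, -.605, 0))
  v <- 0
  for (e in E) {
    p <- e[6] * pi / 180
    xr <- (x - e[4]) * cos(p) + (y - e[5]) * sin(p)
    yr <- -(x - e[4]) * sin(p) + (y - e[5]) * cos(p)
    if ((xr / e[2])^2 + (yr / e[3])^2 <= 1) v <- v + e[1]
  }
  v
}

# brute-force circular convolution (double loop), kernel indexed by
# circular offset via fun(offset)
oracleCircularConv <- function(p, kernelFun) {
  N <- length(p)
  q <- numeric(N)
  for (t in 0:(N - 1)) {
    acc <- 0
    for (l in 0:(N - 1)) {
      off <- ((t - l) %% N)
      acc <- acc + p[l + 1] * kernelFun(off)
    }
    q[t + 1] <- acc
  }
  q
}

# brute-force normal equations for the symmetric deconvolution design:
# full linear-convolution matrix assembled by enumeration, symmetry by
# explicit parameter tying, solved via solve(t(A) %*% A)
oracleDesignTaps <- function(h) {
  m <- length(h)
  n <- (m - 1) %/% 2
  A <- matrix(0, 2 * m - 1, m)
  for (i in seq_len(2 * m - 1)) {
    for (j in seq_len(m)) {
      k <- i - j + 1
      if (k >= 1 && k <= m) A[i, j] <- h[k]
    }
  }
  S <- matrix(0, m, n + 1)
  for (j in seq_len(n + 1)) { S[j, j] <- 1; S[m + 1 - j, j] <- 1 }
  S[n + 1, n + 1] <- 1
  d <- numeric(2 * m - 1); d[m] <- 1
  M <- A %*% S
  x <- solve(t(M) %*% M, t(M) %*% d)
  f <- as.numeric(S %*% x)
  f * 2 / sum(f)
}

# small standard experiment used across tests
phantomExperiment <- function(n = 64, step = 2, maxIterations = 2) {
  ph <- headPhantom(n)
  sg <- forwardProject(ph, seq(0, 180 - step, by = step))
  list(phantom = ph, sino = sg,
       cfg = reconConfig(n, maxIterations = maxIterations))
}
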