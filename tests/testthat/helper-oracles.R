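# Independent brute-force oracles the tests compare the implementation
# against. These deliberately avoid the package's own code paths.

# O(N^2) direct DFT, one-sided power under the documented normalization
# (|X_k|^2 / N, interior bins doubled)
naivePowerSpectrum <- function(x) {
  n <- length(x)
  nb <- floor(n / 2) + 1L
  pw <- numeric(nb)
  for (k in seq_len(nb) - 1L) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1L) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1L) / n))
    pw[k + 1L] <- (re^2 + im^2) / n
  }
  dbl <- if (n %% 2 == 0) seq(2L, nb - 1L) else seq(2L, nb)
  pw[dbl] <- 2 * pw[dbl]
  pw
}

# recursive flood fill, the slow-and-obvious component labeller
floodFillLabels <- function(mask, connectivity = 8) {
  R <- nrow(mask); C <- ncol(mask)
  lab <- matrix(0L, R, C)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (j in seq_len(C)) for (i in seq_len(R)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] >= 1 && q[1] <= R && q[2] >= 1 && q[2] <= C &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# set-arithmetic DICE from scratch on index sets
countingDice <- function(a, b) {
  ia <- which(as.vector(a != 0)); ib <- which(as.vector(b != 0))
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# sort-and-interpolate quartiles (type-7 rule written out by hand)
sortQuartiles <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# point-in-convex-hull by separating-line search: a grid point is outside
# the hull of S iff some line through two points of S strictly separates it
# from all of S (degenerate sets handled by the caller's expectations)
separatingLineOutside <- function(p, S) {
  n <- nrow(S)
  if (n == 1L) return(any(p != S[1L, ]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- S[j, ] - S[i, ]
    crossS <- d[1L] * (S[, 2L] - S[i, 2L]) - d[2L] * (S[, 1L] - S[i, 1L])
    crossP <- d[1L] * (p[2L] - S[i, 2L]) - d[2L] * (p[1L] - S[i, 1L])
    if (all(crossS <= 0) && crossP > 0) return(TRUE)
    if (all(crossS >= 0) && crossP < 0) return(TRUE)
  }
  FALSE
}

bruteHullMask <- function(mask) {
  S <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!nrow(S)) return(out)
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask)))
    out[i, j] <- !separatingLineOutside(c(i, j), S)
  out
}

# small synthetic scene used across tests: fast to simulate, still has
# every ingredient of the default scenario
smallScene <- function(seed = 1, cycles = 3, grid = 32, ...) {
  simulationConfig(gridRows = grid, gridCols = grid,
                   paradigm = stimulusParadigm(cycles = cycles),
                   seed = seed, ...)
}

randomMask <- function(R, C, p = 0.3) matrix(stats::runif(R * C) < p, R, C)
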