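# independent oracles: deliberately naive implementations used to verify
# the package's optimized paths

# brute-force FAST-9/16 segment test evaluated at every pixel; returns the
# (x, y) positions (0-based) of all pixels passing the test
naive_segment_test <- function(m, threshold) {
  cx <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  cy <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  h <- nrow(m); w <- ncol(m)
  hits <- NULL
  for (y in 4:(h - 3)) {
    for (x in 4:(w - 3)) {
      p <- m[y, x]
      d <- sapply(1:16, function(k) m[y + cy[k], x + cx[k]] - p)
      dd <- c(d, d)
      runs <- function(cond) {
        best <- run <- 0
        for (v in cond) {
          run <- if (v) run + 1 else 0
          best <- max(best, run)
        }
        min(best, 16)
      }
      if (runs(dd > threshold) >= 9 || runs(dd < -threshold) >= 9) {
        hits <- rbind(hits, c(x - 1, y - 1))
      }
    }
  }
  hits
}

# O(N*M) nearest-neighbour + mutual cross-check matcher on logical bit
# matrices (rows = descriptors), ties broken toward the lowest index
naive_match <- function(ref_bits, tgt_bits) {
  nr <- nrow(ref_bits); nt <- nrow(tgt_bits)
  if (nr == 0 || nt == 0) {
    return(data.frame(ref_index = integer(0), tgt_index = integer(0),
                      distance = integer(0)))
  }
  D <- matrix(0L, nr, nt)
  for (i in seq_len(nr)) {
    for (j in seq_len(nt)) {
      D[i, j] <- sum(ref_bits[i, ] != tgt_bits[j, ])
    }
  }
  fwd <- apply(D, 1, which.min)   # which.min takes the first (lowest) index
  bwd <- apply(D, 2, which.min)
  keep <- which(bwd[fwd] == seq_len(nr))
  data.frame(ref_index = keep, tgt_index = fwd[keep],
             distance = D[cbind(keep, fwd[keep])])
}

# random packed descriptor set with the pad bytes zeroed
random_descriptor_set <- function(n, L, backend = "ref", seed = 1L) {
  set.seed(seed)
  bits <- matrix(sample(c(TRUE, FALSE), n * L, replace = TRUE), n, L)
  make_descriptor_set(bits, L, backend)
}

make_descriptor_set <- function(bits, L, backend = "ref") {
  nbytes <- ceiling(ceiling(L / 8) / 8) * 8
  n <- nrow(bits)
  bytes <- matrix(as.raw(0), nbytes, max(n, 0))
  for (i in seq_len(n)) {
    padded <- c(bits[i, ], rep(FALSE, nbytes * 8 - L))
    bytes[, i] <- packBits(padded, type = "raw")
  }
  structure(list(bytes = bytes, L = as.integer(L), backend = backend),
            class = "descriptor_set")
}
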