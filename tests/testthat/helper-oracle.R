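# Independent brute-force affine-gap Smith-Waterman (Gotoh) oracle used to
# verify the package's aligner. A gap of length k costs open + k * extend.
sw_oracle <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[av[i - 1], bv[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                   Iy[i - 1, j - 1] + s)
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
  }
  best <- max(M)
  idx <- which(M == best, arr.ind = TRUE)[1, ]
  i <- idx[1]; j <- idx[2]; state <- "M"; matches <- 0; cols <- 0
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] == 0) break
      s <- submat[av[i - 1], bv[j - 1]]
      cols <- cols + 1
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      prev <- M[i, j] - s
      if (abs(prev - M[i - 1, j - 1]) < 1e-9) state <- "M"
      else if (abs(prev - Ix[i - 1, j - 1]) < 1e-9) state <- "Ix"
      else state <- "Iy"
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      cols <- cols + 1
      if (abs(Ix[i, j] - (M[i - 1, j] - open - ext)) < 1e-9) state <- "M"
      i <- i - 1
    } else {
      cols <- cols + 1
      if (abs(Iy[i, j] - (M[i, j - 1] - open - ext)) < 1e-9) state <- "M"
      j <- j - 1
    }
  }
  list(score = best, identity = 100 * matches / cols, cols = cols)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Independent ordinary-least-squares oracle via the normal equations.
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}
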