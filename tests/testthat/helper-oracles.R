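# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

DNA4 <- c("A", "C", "G", "T")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randSeq <- function(n, alphabet = DNA4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force affine-gap local alignment score (Gotoh, full matrices)
oracleSwScore <- function(q, s, mat, gapOpen, gapExtend) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExtend, E[i, j - 1] - gapExtend)
      F[i, j] <- max(H[i - 1, j] - gapOpen - gapExtend, F[i - 1, j] - gapExtend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive enumeration of maximal common substrings of length >= minLen
oracleRepeats <- function(a, b, minLen) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  rows <- list(); k <- 0L
  for (i in seq_along(ac)) {
    for (j in seq_along(bc)) {
      if (ac[i] != bc[j]) next
      if (i > 1L && j > 1L && ac[i - 1L] == bc[j - 1L]) next
      len <- 0L
      while (i + len <= length(ac) && j + len <= length(bc) &&
             ac[i + len] == bc[j + len]) len <- len + 1L
      if (len >= minLen) {
        k <- k + 1L
        rows[[k]] <- data.frame(core = substr(a, i, i + len - 1L),
                                left_start = i, right_start = j,
                                length = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(data.frame(core = character(), left_start = integer(),
                            right_start = integer(), length = integer(),
                            stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df[order(-df$length, df$left_start, df$right_start), , drop = FALSE]
}

# union-find connected components over node names
oracleComponents <- function(nodes, from, to) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_along(from)) {
    ri <- find(which(nodes == from[k]))
    rj <- find(which(nodes == to[k]))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  unname(split(nodes, roots))
}

# one planted tRNA-end lysogen, used by several suites
makeLysogen <- function(seed, coreLen = 20, hostLen = 6000,
                        cassetteLen = 600, hostGc = 65, phageGc = 60,
                        trnaStrand = "+", cdsDensity = 0.5) {
  host <- generateHostGenome(hostGenomeSpec(
    length = hostLen, gcTarget = hostGc,
    trnaGenes = data.frame(position = round(hostLen / 2), length = 76,
                           name = "tRNA-Met(CAT)", strand = trnaStrand,
                           stringsAsFactors = FALSE),
    cdsDensity = cdsDensity), seed)
  lys <- simulateIntegration(host, prophageSpec(
    length = cassetteLen, gcTarget = phageGc, attCoreLength = coreLen),
    "tRNA-Met(CAT)", seed + 100000L)
  lys$host <- host
  lys
}
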