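# Shared fixtures and independent oracles, built in code at test time.

AA <- aa_alphabet()

random_protein <- function(n, prob = NULL) {
  paste(sample(AA, n, replace = TRUE, prob = prob), collapse = "")
}

# mutate k distinct positions to a different random residue
mutate_at <- function(seq, positions) {
  res <- strsplit(seq, "")[[1]]
  for (p in positions) res[p] <- sample(setdiff(AA, res[p]), 1)
  paste(res, collapse = "")
}

# Independent affine-gap Smith-Waterman oracle: plain-R Gotoh recursion,
# score only. Written separately from the package's alignment path.
sw_oracle <- function(a, b, mat, open = 11, extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in a match
  Ix <- matrix(NEG, n + 1, m + 1)    # gap in y (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)    # gap in x (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
      s <- mat[x[i], y[j]]
      M[i + 1, j + 1] <- max(0,
                             s + max(M[i, j], Ix[i, j], Iy[i, j]))
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# exhaustive local-alignment oracle for very short strings: enumerate every
# pair of substrings and every gapped alignment between them by recursion
enum_oracle <- function(a, b, mat, open = 11, extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  align_score <- function(xs, ys) {
    # best global alignment score of xs vs ys via exhaustive recursion with
    # explicit gap-state bookkeeping
    rec <- function(i, j, state) {
      if (i > length(xs) && j > length(ys)) return(0)
      out <- -Inf
      if (i <= length(xs) && j <= length(ys))
        out <- max(out, mat[xs[i], ys[j]] + rec(i + 1, j + 1, 0L))
      if (i <= length(xs)) {
        pen <- if (state == 1L) extend else open + extend
        out <- max(out, -pen + rec(i + 1, j, 1L))
      }
      if (j <= length(ys)) {
        pen <- if (state == 2L) extend else open + extend
        out <- max(out, -pen + rec(i, j + 1, 2L))
      }
      out
    }
    rec(1, 1, 0L)
  }
  best <- 0
  for (i1 in seq_along(x)) for (i2 in i1:length(x))
    for (j1 in seq_along(y)) for (j2 in j1:length(y))
      best <- max(best, align_score(x[i1:i2], y[j1:j2]))
  best
}

# independent matrix exponential: Taylor series with scaling and squaring
expm_oracle <- function(Q, t, k = 8L) {
  A <- Q * (t / 2^k)
  P <- diag(nrow(Q)); term <- diag(nrow(Q))
  for (i in 1:40) { term <- term %*% A / i; P <- P + term }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# a reduced family configuration for fast pipeline tests
small_sim_config <- function(seed = 11L, ...) {
  sim_config(seed = seed,
             species = .subset(capclade_species(), 1:4),
             copies = rep(list(list(c(1L, 1L), c(1L, 1L), c(1L, 1L))), 3),
             presence = list(c(4L, 4L, 4L), c(4L, 4L, 3L), c(4L, 3L, 2L)),
             bias = list(n = 2L, weight = 0.5, target = NULL,
                         stem = 0.35, tip = 0.15),
             ...)
}

capclade_species <- function() {
  sim_config()$species
}

# anchored multiple alignment for a set of records (drops rows that fail to
# anchor, as the pipeline does)
anchor_stack <- function(records) {
  alns <- lapply(records, align_to_reference)
  trimmed <- lapply(alns, function(a)
    tryCatch(trim_core(a), error = function(e) NULL))
  stack_alignment(trimmed[!vapply(trimmed, is.null, TRUE)])
}
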