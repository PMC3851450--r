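## Independent oracles and fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, freq = rep(1 / 20, 20)) {
  paste(sample(AA20, len, replace = TRUE, prob = freq), collapse = "")
}

random_records <- function(n, len_range = c(50, 200), freq = rep(1 / 20, 20),
                           prefix = "r") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  protein_records(id = paste0(prefix, seq_len(n)),
                  sequence = vapply(lens, random_seq, character(1), freq = freq))
}

## Point-mutate a fraction of residues (creates a high-identity homolog).
mutate_seq <- function(s, rate = 0.10) {
  ch <- strsplit(s, "")[[1]]
  k <- max(1L, round(length(ch) * rate))
  pos <- sample(seq_along(ch), k)
  ch[pos] <- vapply(ch[pos], function(old) sample(setdiff(AA20, old), 1),
                    character(1))
  paste(ch, collapse = "")
}

## Naive direct-summation pseudo amino-acid composition: standardizes the
## two scales and evaluates every correlation tier with explicit loops.
## Deliberately written independently of the package implementation.
naive_pseaac <- function(s, lam = 5, w = 0.1,
                         h1raw = plastidclass::TANFORD_HYDROPHOBICITY,
                         h2raw = plastidclass::HOPP_WOODS_HYDROPHILICITY) {
  std <- function(v) {
    v <- v[AA20]
    m <- sum(v) / 20
    sdev <- sqrt(sum((v - m)^2) / 20)
    (v - m) / sdev
  }
  h1 <- std(h1raw); h2 <- std(h2raw)
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  f <- numeric(20); names(f) <- AA20
  for (c in ch) f[c] <- f[c] + 1
  f <- f / L
  theta <- numeric(2 * lam)
  for (tau in 1:lam) {
    s1 <- 0; s2 <- 0
    for (i in 1:(L - tau)) {
      s1 <- s1 + h1[ch[i]] * h1[ch[i + tau]]
      s2 <- s2 + h2[ch[i]] * h2[ch[i + tau]]
    }
    theta[2 * tau - 1] <- s1 / (L - tau)
    theta[2 * tau] <- s2 / (L - tau)
  }
  D <- sum(f) + w * sum(theta)
  unname(c(f / D, w * theta / D))
}

## Gotoh global affine-gap alignment oracle (gap of length k costs
## open + ext*k, matching the package's alignment settings). Returns the
## optimal score and the percent identity of one optimal traceback.
gotoh_identity <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  ## traceback one optimal path, counting identities and columns
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  ident <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1) {
      if (A[i - 1] == B[j - 1]) ident <- ident + 1L
      sc <- S[A[i - 1], B[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      cand <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                Y[i - 1, j] - open - ext)
      state <- which.max(cand)
      i <- i - 1
    } else {
      cand <- c(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                X[i, j - 1] - open - ext)
      state <- c(1, 3, 2)[which.max(cand)]
      j <- j - 1
    }
  }
  list(score = score, identity = 100 * ident / cols)
}

## Homology-reduction fixture: n_seed founder sequences plus n_copies
## mutated homologs each (~90% identity to their founder).
homology_fixture <- function(n_seed = 6, n_copies = 2, len = 160,
                             prefix = "f") {
  seqs <- character(0); ids <- character(0)
  for (s in seq_len(n_seed)) {
    founder <- random_seq(len)
    seqs <- c(seqs, founder); ids <- c(ids, sprintf("%s%d_seed", prefix, s))
    for (k in seq_len(n_copies)) {
      seqs <- c(seqs, mutate_seq(founder, 0.10))
      ids <- c(ids, sprintf("%s%d_copy%d", prefix, s, k))
    }
  }
  protein_records(id = ids, sequence = seqs)
}

## Tiny deterministic trainer/predictor pair for CV plumbing tests:
## nearest-class-centroid (no SVM), so fold mechanics are tested cheaply.
centroid_trainer <- function(x, y) {
  lapply(split(as.data.frame(x), y), colMeans)
}
centroid_predictor <- function(model, x) {
  d <- sapply(model, function(ctr) colSums((t(x) - ctr)^2))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(model)))
  colnames(d)[apply(d, 1, which.min)]
}
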