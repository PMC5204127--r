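# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_residues <- function(n, alphabet = AA20, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

rdirich <- function(n, alpha = 1) {
  x <- rgamma(n, shape = alpha)
  x / sum(x)
}

# a random (valid) profile HMM object for oracle tests
random_hmm <- function(L, concentrate = 1) {
  probs <- sapply(seq_len(L), function(k) rdirich(21, concentrate))
  bg <- rdirich(21, 5)
  tr <- sapply(seq_len(max(L - 1, 1)), function(k) {
    m <- rdirich(3); i <- rdirich(2); d <- rdirich(2)
    c(MM = m[1], MI = m[2], MD = m[3], IM = i[1], II = i[2],
      DM = d[1], DD = d[2])
  })
  structure(list(length = L,
                 match_probs = matrix(probs, 21, L,
                                      dimnames = list(confeax_alphabet(), NULL)),
                 transitions = matrix(tr, 7, max(L - 1, 1),
                                      dimnames = list(c("MM", "MI", "MD", "IM",
                                                        "II", "DM", "DD"), NULL)),
                 background = stats::setNames(bg, confeax_alphabet()),
                 entry = 1 / L, exit = 1 / L, calibration = NULL),
            class = "confeax_hmm")
}

# Exhaustive enumeration of every legal local path of the profile HMM over a
# sequence: entry into any match state at any residue, M/I emit one residue
# (insert log-odds 0), D silent, exit from any match state. Returns all path
# log-odds in bits.
enumerate_path_scores <- function(hmm, seq) {
  codes <- match(strsplit(seq, "")[[1]], confeax_alphabet())
  n <- length(codes)
  L <- hmm$length
  mlo <- log2(hmm$match_probs) - log2(hmm$background)
  mlo[21, ] <- 0
  t7 <- log2(hmm$transitions)
  lentry <- log2(hmm$entry)
  lexit <- log2(hmm$exit)
  scores <- numeric(0)
  # state: "M", "I" (at node k), or "D" (at node k); i = residues consumed
  recurse <- function(state, k, i, acc) {
    if (state == "M") scores[length(scores) + 1] <<- acc + lexit
    if (state == "M" && k < L) {
      if (i < n) recurse("M", k + 1, i + 1,
                         acc + t7["MM", k] + mlo[codes[i + 1], k + 1])
      if (i < n) recurse("I", k, i + 1, acc + t7["MI", k])
      recurse("D", k + 1, i, acc + t7["MD", k])
    }
    if (state == "I") {
      if (i < n) recurse("I", k, i + 1, acc + t7["II", k])
      if (i < n) recurse("M", k + 1, i + 1,
                         acc + t7["IM", k] + mlo[codes[i + 1], k + 1])
    }
    if (state == "D" && k < L) {
      if (i < n) recurse("M", k + 1, i + 1,
                         acc + t7["DM", k] + mlo[codes[i + 1], k + 1])
      recurse("D", k + 1, i, acc + t7["DD", k])
    }
  }
  for (i0 in seq_len(n)) for (k0 in seq_len(L))
    recurse("M", k0, i0, lentry + mlo[codes[i0], k0])
  scores
}

log2sumexp <- function(x) {
  m <- max(x)
  m + log2(sum(2^(x - m)))
}

# Brute-force average-linkage reference: average distances recomputed from
# the original matrix at every step; same tie rule (lexicographically
# smallest pair of cluster representatives).
upgma_reference <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i) i)   # member index lists
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      pa <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
      if (is.null(best) || avg < best$avg ||
          (avg == best$avg && (pa[1] < best$pa[1] ||
                               (pa[1] == best$pa[1] && pa[2] < best$pa[2]))))
        best <- list(a = a, b = b, avg = avg, pa = pa)
    }
    merge[step, ] <- sort(c(codes[best$a], codes[best$b]))
    height[step] <- best$avg / 2
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    codes[best$a] <- step
    clusters[[best$b]] <- NULL
    codes <- codes[-best$b]
  }
  list(merge = merge, height = height)
}

# Plain global Needleman-Wunsch score with affine gaps (open + (g-1)*ext)
# over a substitution matrix; independent of the package's aligner.
nw_score_oracle <- function(s1, s2, S, gopen = 11, gext = 1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n1 + 1, n2 + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n1 + 1)) X[i, 1] <- -gopen - (i - 2) * gext
  for (j in 2:(n2 + 1)) Y[1, j] <- -gopen - (j - 2) * gext
  for (i in 2:(n1 + 1)) for (j in 2:(n2 + 1)) {
    M[i, j] <- S[a[i - 1], b[j - 1]] + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                           Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] - gopen, X[i - 1, j] - gext, Y[i - 1, j] - gopen)
    Y[i, j] <- max(M[i, j - 1] - gopen, X[i, j - 1] - gopen, Y[i, j - 1] - gext)
  }
  max(M[n1 + 1, n2 + 1], X[n1 + 1, n2 + 1], Y[n1 + 1, n2 + 1])
}

# score an existing pairwise alignment (two gapped rows) with the same
# affine convention
score_pairwise_alignment <- function(r1, r2, S, gopen = 11, gext = 1) {
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  sc <- 0; gap1 <- FALSE; gap2 <- FALSE
  for (t in seq_along(a)) {
    if (a[t] != "-" && b[t] != "-") {
      sc <- sc + S[a[t], b[t]]; gap1 <- gap2 <- FALSE
    } else if (a[t] == "-") {
      sc <- sc - if (gap1) gext else gopen; gap1 <- TRUE; gap2 <- FALSE
    } else {
      sc <- sc - if (gap2) gext else gopen; gap2 <- TRUE; gap1 <- FALSE
    }
  }
  sc
}

# small helper: sequence records of i.i.d. uniform background
background_family <- function(n_seqs, len, seed) {
  set.seed(seed)
  seq_records(id = sprintf("bg%02d", seq_len(n_seqs)),
              residues = vapply(seq_len(n_seqs),
                                function(i) random_residues(len), ""))
}
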