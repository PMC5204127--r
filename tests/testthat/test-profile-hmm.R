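mkaln <- function(rows) {
  structure(list(rows = rows, n_cols = nchar(rows[[1]])),
            class = "confeax_alignment")
}

test_that("build_hmm: degenerate gapless alignment and stochasticity invariants", {
  aln <- mkaln(stats::setNames(rep("MKVWENLAQD", 5), paste0("r", 1:5)))
  hmm <- build_hmm(aln)
  expect_equal(hmm$length, 10)
  cons <- strsplit("MKVWENLAQD", "")[[1]]
  for (k in 1:10)
    expect_equal(names(which.max(hmm$match_probs[1:20, k])), cons[k])
  expect_silent(confeax:::validate_hmm(hmm))
})

test_that("columns under the match threshold become insert states", {
  rows <- c(r1 = "MKVAWENLAQD", r2 = "MKV-WENLAQD", r3 = "MKV-WENLAQD",
            r4 = "MKV-WENLAQD", r5 = "MKV-WENLAQD")  # col 4: 20% occupied
  hmm <- build_hmm(mkaln(rows), match_threshold = 0.5)
  expect_equal(hmm$length, 10)

  expect_error(build_hmm(mkaln(c(a = "M", b = "M"))), "at least 2 match")
  expect_error(build_hmm(mkaln(c(a = "MK"))), "at least 2 alignment rows")
})

test_that("built models always satisfy the stochasticity invariants", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    w <- sample(6:15, 1)
    rows <- vapply(seq_len(n), function(i) {
      v <- sample(c(AA20, "-"), w, replace = TRUE,
                  prob = c(rep(0.9 / 20, 20), 0.1))
      paste(v, collapse = "")
    }, "")
    names(rows) <- paste0("r", seq_len(n))
    aln <- mkaln(rows)
    occ <- colMeans(do.call(rbind, strsplit(rows, "")) != "-")
    if (sum(occ >= 0.5) < 2) next
    expect_silent(confeax:::validate_hmm(build_hmm(aln)))
  }
})

test_that("Viterbi and forward equal the exhaustive path oracle", {
  set.seed(17)
  for (rep in 1:25) {
    L <- sample(2:4, 1)
    hmm <- random_hmm(L)
    n <- sample(3:7, 1)
    seq <- random_residues(n, alphabet = c("A", "C", "D", "E"))
    paths <- enumerate_path_scores(hmm, seq)
    v <- viterbi(hmm, seq)
    expect_equal(v$score_bits, max(paths), tolerance = 1e-9)
    expect_equal(forward(hmm, seq), log2sumexp(paths), tolerance = 1e-9)
  }
})

test_that("forward >= viterbi everywhere; near-deterministic model scores as the log-odds sum", {
  set.seed(23)
  for (rep in 1:20) {
    hmm <- random_hmm(sample(2:5, 1))
    seq <- random_residues(sample(4:12, 1))
    expect_gte(forward(hmm, seq) + 1e-9, viterbi(hmm, seq)$score_bits)
  }

  # consensus sequence along a near-deterministic model: all-match path
  cons <- "MKVWEN"
  aln <- mkaln(stats::setNames(rep(cons, 20), paste0("r", 1:20)))
  hmm <- build_hmm(aln, pseudocount = 1e-4)
  v <- viterbi(hmm, cons)
  mlo <- log2(hmm$match_probs) - log2(hmm$background)
  codes <- match(strsplit(cons, "")[[1]], rownames(mlo))
  expected <- sum(mlo[cbind(codes, 1:6)]) +
    sum(log2(hmm$transitions["MM", ])) + 2 * log2(1 / 6)
  expect_equal(v$score_bits, expected, tolerance = 1e-6)
  expect_equal(c(v$start, v$end), c(0L, 6L))
})

test_that("a sequence with no positive-scoring window scores at most ~0", {
  aln <- mkaln(stats::setNames(rep("WWWWWWWW", 10), paste0("r", 1:10)))
  hmm <- build_hmm(aln, pseudocount = 1e-3)
  v <- viterbi(hmm, "AAAAAAAAAAAA")
  expect_lte(v$score_bits, 0)
})

test_that("Gumbel calibration recovers known parameters within 5%", {
  set.seed(41)
  mu <- 2; lambda <- 0.7
  x <- mu - log(-log(runif(5000))) / lambda
  fit <- confeax:::fit_gumbel(x)
  expect_lt(abs(fit$mu - mu) / mu, 0.05)
  expect_lt(abs(fit$lambda - lambda) / lambda, 0.05)

  expect_error(confeax:::fit_gumbel(rep(1, 200)), "degenerate")
})

test_that("E-values: monotone decreasing in score, closed form at S = mu", {
  hmm <- random_hmm(3)
  hmm$calibration <- list(mu = 4, lambda = 0.6, n_random = 200)
  s <- seq(-5, 40, by = 0.5)
  e <- hmm_evalue(hmm, s, n_targets = 100)
  expect_true(all(diff(e) <= 0))
  expect_equal(hmm_evalue(hmm, 4, n_targets = 100), 100)  # clipped at n
  expect_true(all(e >= 0 & e <= 100))
})

test_that("search finds carriers, skips non-carriers, resolves repeats", {
  set.seed(55)
  motif <- "WKENLAQDCF"
  carriers <- vapply(1:30, function(i)
    paste0(random_residues(80), motif, random_residues(80)), "")
  nonc <- vapply(1:10, function(i) random_residues(170), "")
  seqs <- seq_records(sprintf("s%02d", 1:40), c(carriers, nonc))
  aln <- mkaln(stats::setNames(rep(motif, 10), paste0("t", 1:10)))
  # the null/background must describe the searched family, not the 10
  # instance strings
  hmm <- calibrate_hmm(build_hmm(aln, background = residue_background(seqs)),
                       nchar(seqs$residues), seed = 1)
  hits <- hmm_search(hmm, seqs, threshold = list(evalue = 0.01))
  carriers_hit <- sum(sprintf("s%02d", 1:30) %in% hits$seq_id)
  false_hits <- sum(hits$seq_id %in% sprintf("s%02d", 31:40))
  expect_gte(carriers_hit, 27)
  expect_lte(false_hits, 1)

  # +Inf bit threshold: empty
  expect_equal(nrow(hmm_search(hmm, seqs, threshold = list(bits = Inf))), 0)

  # two planted copies in one sequence -> two non-overlapping hits
  two <- seq_records("dbl", paste0(random_residues(50), motif,
                                   random_residues(50), motif,
                                   random_residues(50)))
  h2 <- hmm_search(hmm, rbind(seqs, two), threshold = list(evalue = 0.01))
  h2 <- h2[h2$seq_id == "dbl", ]
  expect_equal(nrow(h2), 2)
  h2 <- h2[order(h2$start), ]
  expect_gte(h2$start[2], h2$end[1])
})

test_that("iteration converges and does not lose a strong feature", {
  sim <- simulate_family(sim_config_recovery(), seed = 12)
  mots <- discover_motifs(sim$seqs, max_motifs = 1, seed = 12)
  res <- confeax_iterate(mots[[1]], sim$seqs, seed = 12)
  expect_true(any(res$trace$converged))
  expect_lte(max(res$trace$iteration), 20)
  rec_final <- evaluate_recovery(sim$truth, hits = res$hits)$site_recall
  rec_em <- evaluate_recovery(sim$truth, hits = mots[[1]]$hits)$site_recall
  expect_gte(rec_final, rec_em)
  expect_true(all(res$trace$jaccard >= 0 & res$trace$jaccard <= 1))

  # re-running from the converged hits reaches the fixed point immediately
  motif2 <- mots[[1]]
  motif2$hits <- res$hits[!is.na(res$hits$evalue) &
                            res$hits$evalue <= 0.1, , drop = FALSE]
  res2 <- confeax_iterate(motif2, sim$seqs, seed = 12)
  expect_equal(res2$trace$jaccard[1], 1)
  expect_true(res2$trace$converged[1])

  # byte-identical rerun under the same seed
  res3 <- confeax_iterate(mots[[1]], sim$seqs, seed = 12)
  expect_identical(res3$hits, res$hits)
  expect_identical(res3$trace, res$trace)
})

test_that("iteration errors when the seed motif has too few hits", {
  sim <- simulate_family(sim_config_recovery(), seed = 12)
  mots <- discover_motifs(sim$seqs, max_motifs = 1, seed = 12)
  weak <- mots[[1]]
  weak$hits <- weak$hits[1, , drop = FALSE]
  expect_error(confeax_iterate(weak, sim$seqs, seed = 1), "at least 2 hits")
})
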