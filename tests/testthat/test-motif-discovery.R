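test_that("score_window matches the closed form and a naive loop oracle", {
  bg <- residue_background(uniform = TRUE)
  # deterministic columns: probability ~1 on one letter, uniform background
  pwm <- confeax:::seed_pwm(confeax:::encode_residues("WKV"), bg)
  # closed form for the seeding scheme: p(hit) = 0.7 * (1 - bgX)
  expected <- 3 * log2(0.7 * (1 - bg["X"]) / bg["W"])
  expect_equal(score_window(pwm, "WKV"), unname(expected), tolerance = 1e-12)

  # all-X window scores exactly 0
  expect_equal(score_window(pwm, "XXX"), 0)

  # mismatched width errors
  expect_error(score_window(pwm, "WKVA"), "width")

  # arbitrary PWM vs per-column loop oracle
  set.seed(7)
  for (rep in 1:20) {
    w <- sample(4:8, 1)
    counts <- matrix(rgamma(21 * w, 1), 21, w)
    pwm <- confeax:::pwm_from_counts(counts, residue_background(uniform = TRUE))
    win <- random_residues(w)
    oracle <- 0
    for (j in seq_len(w)) {
      a <- substr(win, j, j)
      oracle <- oracle + unname(log2(pwm$probs[a, j] / pwm$background[a]))
    }
    expect_equal(score_window(pwm, win), oracle, tolerance = 1e-9)
  }
})

test_that("PWM invariants: columns sum to 1, entries positive, X pinned", {
  set.seed(1)
  counts <- matrix(rgamma(21 * 6, 0.5), 21, 6)
  bg <- residue_background(uniform = TRUE)
  pwm <- confeax:::pwm_from_counts(counts, bg)
  expect_true(all(abs(colSums(pwm$probs) - 1) < 1e-9))
  expect_true(all(pwm$probs > 0))
  expect_equal(unname(pwm$probs["X", ]), rep(unname(bg["X"]), 6))
})

test_that("EM log likelihood is monotone non-decreasing from any start", {
  set.seed(11)
  for (rep in 1:10) {
    seqs <- background_family(4, 60, seed = 100 + rep)
    bg <- residue_background(seqs)
    w <- sample(4:6, 1)
    start <- substr(seqs$residues[1], 1, w)
    state <- list(pwm = confeax:::seed_pwm(confeax:::encode_residues(start), bg),
                  site_prior = 1 / 60)
    ll <- numeric(30)
    for (it in 1:30) {
      state2 <- em_step(state$pwm, state$site_prior, seqs)
      ll[it] <- state2$loglik
      state <- state2
    }
    expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("EM at a fixed point of a noiseless dataset leaves loglik unchanged", {
  # identical sequences containing one exact repeat of the motif
  seqs <- seq_records(sprintf("s%d", 1:5), rep("AAAAKVWENAAAA", 5))
  bg <- residue_background(uniform = TRUE)
  state <- list(pwm = confeax:::seed_pwm(confeax:::encode_residues("KVWEN"), bg),
                site_prior = 1 / 13)
  for (it in 1:200) state <- em_step(state$pwm, state$site_prior, seqs)
  ll1 <- em_step(state$pwm, state$site_prior, seqs)$loglik
  state2 <- em_step(state$pwm, state$site_prior, seqs)
  ll2 <- em_step(state2$pwm, state2$site_prior, seqs)$loglik
  expect_lt(abs(ll2 - ll1), 1e-9)
})

test_that("EM from a shared 6-mer seed converges with both sites confident", {
  seqs <- seq_records(c("a", "b"),
                      c("MPQRSTGACDEFHIKNVWYL", "HIKLNMGACDEFWYTSRQPV"))
  bg <- residue_background(seqs)
  enc <- confeax:::encode_seqs(seqs)
  fit <- confeax:::em_refine(enc, confeax:::seed_pwm(
    confeax:::encode_residues("GACDEF"), bg), 1 / 20)
  sites <- confeax:::extract_sites(enc, fit$pwm, fit$site_prior)
  expect_equal(nrow(sites), 2)
  expect_true(all(sites$posterior > 0.99))
  # brute-force posterior check: the shared 6-mer must dominate each sequence
  lr <- confeax:::pwm_logratio(fit$pwm)
  for (s in 1:2) {
    llrs <- vapply(seq_len(length(enc[[s]]) - 5), function(i)
      sum(lr[cbind(enc[[s]][i:(i + 5)], 1:6)]), 1.0)
    expect_equal(which.max(llrs), sites$start1[sites$seq_idx == s])
  }
})

test_that("discovery recovers a fully conserved planted 10-mer", {
  sim <- simulate_family(sim_config_recovery(), seed = 5)
  mots <- discover_motifs(sim$seqs, max_motifs = 1, seed = 5)
  expect_length(mots, 1)
  rec <- evaluate_recovery(sim$truth, hits = mots[[1]]$hits)
  expect_gte(rec$site_recall, 0.9)
  expect_gte(rec$site_precision, 0.9)
  # consensus of the top motif contains the planted consensus
  expect_match(pwm_consensus(mots[[1]]$pwm), "WIRQDGKHTC")
})

test_that("repeats-allowed model finds three copies in one sequence", {
  set.seed(9)
  motif <- "KVWENLAQDC"
  flank <- function(n) random_residues(n)
  one <- paste0(flank(40), motif, flank(35), motif, flank(50), motif, flank(30))
  others <- vapply(1:9, function(i)
    paste0(flank(60), motif, flank(60)), "")
  seqs <- seq_records(sprintf("s%02d", 1:10), c(one, others))
  mots <- discover_motifs(seqs, max_motifs = 1, width_range = c(10, 10),
                          seed = 2)
  expect_length(mots, 1)
  h1 <- mots[[1]]$hits[mots[[1]]$hits$seq_id == "s01", ]
  expect_equal(nrow(h1), 3)
  # non-overlapping
  h1 <- h1[order(h1$start), ]
  expect_true(all(h1$start[-1] >= h1$end[-nrow(h1)]))
})

test_that("motifs are masked before the next is sought (no overlap)", {
  set.seed(13)
  m1 <- "KVWENLAQDC"; m2 <- "PHGTRSMYEF"
  seqs <- seq_records(sprintf("s%02d", 1:12), vapply(1:12, function(i)
    paste0(random_residues(40), m1, random_residues(40), m2,
           random_residues(40)), ""))
  mots <- discover_motifs(seqs, max_motifs = 3, width_range = c(10, 10),
                          seed = 3)
  expect_gte(length(mots), 2)
  h1 <- mots[[1]]$hits; h2 <- mots[[2]]$hits
  for (sid in intersect(h1$seq_id, h2$seq_id)) {
    a <- h1[h1$seq_id == sid, ]; b <- h2[h2$seq_id == sid, ]
    for (i in seq_len(nrow(a)))
      expect_true(all(b$end <= a$start[i] | b$start >= a$end[i]))
  }
})

test_that("pure background yields no accepted motif in at least 9 of 10 seeds", {
  clean <- 0
  for (s in 1:10) {
    seqs <- background_family(20, 100, seed = 100 + s)
    mots <- discover_motifs(seqs, max_motifs = 1, seed = s)
    clean <- clean + (length(mots) == 0)
  }
  expect_gte(clean, 9)
})

test_that("discovery is deterministic given the seed", {
  sim <- simulate_family(sim_config_recovery(), seed = 8)
  m1 <- discover_motifs(sim$seqs, max_motifs = 1, seed = 4)
  m2 <- discover_motifs(sim$seqs, max_motifs = 1, seed = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_model_json(m1[[1]], f1)
  write_model_json(m2[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("significance is small for a planted motif, large on background", {
  sim <- simulate_family(sim_config_recovery(), seed = 6)
  mots <- discover_motifs(sim$seqs, max_motifs = 1, seed = 6)
  expect_lt(motif_significance(mots[[1]], sim$seqs, seed = 1), 0.05)

  # a motif claimed on pure background data is not significant: under the
  # exchangeable shuffle null the significance is roughly uniform
  bgseqs <- background_family(20, 120, seed = 77)
  sigs <- vapply(1:3, function(s)
    motif_significance(mots[[1]], bgseqs, seed = s), 1.0)
  expect_gte(stats::median(sigs), 0.2)
  expect_error(motif_significance(mots[[1]], sim$seqs, n_shuffles = 5), ">= 20")
})
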