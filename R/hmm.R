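# --- model construction ---------------------------------------------------

# Henikoff position-based sequence weights; gaps contribute nothing.
# Weights are normalized to sum to the number of rows.
henikoff_weights <- function(m) {
  nr <- nrow(m)
  w <- numeric(nr)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-"]
    if (!length(res)) next
    tb <- table(res)
    r <- length(tb)
    contrib <- 1 / (r * as.numeric(tb[col]))
    contrib[col == "-"] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) rep(1, nr) else w / sum(w) * nr
}

#' Build a profile HMM from an instance alignment
#'
#' Columns with occupancy at or above `match_threshold` become match states;
#' the rest are insert states. Emissions and transitions are estimated from
#' Henikoff position-weighted counts with Laplace (+1) pseudocounts. The
#' model is local: uniform entry into and exit from any match state; insert
#' states emit the background (zero log-odds); `X` scores zero log-odds in
#' match states.
#'
#' @param aln a `confeax_alignment` with at least 2 rows.
#' @param match_threshold occupancy for a column to be a match state
#'   (default 0.5).
#' @param background 21 background frequencies; defaults to the residue
#'   composition of the alignment.
#' @param pseudocount Laplace pseudocount for emissions and transitions.
#' @return An object of class `confeax_hmm`.
#' @export
build_hmm <- function(aln, match_threshold = 0.5, background = NULL,
                      pseudocount = 1) {
  m <- alignment_char_matrix(aln)
  if (nrow(m) < 2) stop("profile HMM needs at least 2 alignment rows", call. = FALSE)
  occ <- colMeans(m != "-")
  match_cols <- which(occ >= match_threshold)
  if (length(match_cols) == 0)
    stop("no match columns at this occupancy threshold", call. = FALSE)
  L <- length(match_cols)
  if (L < 2) stop("profile HMM needs at least 2 match columns", call. = FALSE)
  if (is.null(background)) {
    res <- m[m != "-"]
    background <- residue_background(paste(res, collapse = ""))
  }
  bgx <- background[21]
  wts <- henikoff_weights(m)

  # match emissions
  emit <- matrix(0, 21, L, dimnames = list(.AA, NULL))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    cnt <- numeric(20)
    for (i in seq_len(nrow(m))) {
      a <- col[i]
      if (a != "-" && a != "X") cnt[.AA_CODE[a]] <- cnt[.AA_CODE[a]] + wts[i]
    }
    p <- (cnt + pseudocount) / sum(cnt + pseudocount) * (1 - bgx)
    emit[1:20, k] <- p
    emit[21, k] <- bgx
  }

  # transition counts between consecutive match nodes; inserts between them
  tc <- matrix(pseudocount, 7, max(L - 1, 1),
               dimnames = list(c("MM", "MI", "MD", "IM", "II", "DM", "DD"), NULL))
  if (L >= 2) {
    for (i in seq_len(nrow(m))) {
      stt <- ifelse(m[i, match_cols] == "-", "D", "M")
      for (k in seq_len(L - 1)) {
        gapcols <- match_cols[k + 1] - match_cols[k] - 1L
        between <- if (gapcols > 0) m[i, (match_cols[k] + 1L):(match_cols[k + 1] - 1L)]
                   else character(0)
        nins <- sum(between != "-")
        from <- stt[k]; to <- stt[k + 1]
        if (nins > 0 && from == "M") {
          tc["MI", k] <- tc["MI", k] + wts[i]
          if (nins > 1) tc["II", k] <- tc["II", k] + (nins - 1) * wts[i]
          if (to == "M") tc["IM", k] <- tc["IM", k] + wts[i]
          # I -> D is disallowed in this topology; such rows contribute the
          # insert run only
        } else {
          key <- paste0(from, to)
          if (key %in% rownames(tc)) tc[key, k] <- tc[key, k] + wts[i]
        }
      }
    }
  }
  trans <- tc
  trans[c("MM", "MI", "MD"), ] <- sweep(tc[c("MM", "MI", "MD"), , drop = FALSE], 2,
                                        colSums(tc[c("MM", "MI", "MD"), , drop = FALSE]), "/")
  trans[c("IM", "II"), ] <- sweep(tc[c("IM", "II"), , drop = FALSE], 2,
                                  colSums(tc[c("IM", "II"), , drop = FALSE]), "/")
  trans[c("DM", "DD"), ] <- sweep(tc[c("DM", "DD"), , drop = FALSE], 2,
                                  colSums(tc[c("DM", "DD"), , drop = FALSE]), "/")

  structure(list(length = L, match_probs = emit, transitions = trans,
                 background = stats::setNames(as.numeric(background), .AA),
                 entry = 1 / L, exit = 1 / L, match_cols = match_cols,
                 calibration = NULL),
            class = "confeax_hmm")
}

#' @export
print.confeax_hmm <- function(x, ...) {
  cal <- if (is.null(x$calibration)) "uncalibrated"
         else sprintf("Gumbel mu %.2f lambda %.3f", x$calibration$mu,
                      x$calibration$lambda)
  cat(sprintf("Profile HMM: %d match states, local mode, %s\n", x$length, cal))
  invisible(x)
}

validate_hmm <- function(hmm) {
  stopifnot(inherits(hmm, "confeax_hmm"), hmm$length >= 2)
  if (any(abs(colSums(hmm$match_probs) - 1) > 1e-9))
    stop("match emission rows must sum to 1", call. = FALSE)
  tr <- hmm$transitions
  ok <- abs(colSums(tr[c("MM", "MI", "MD"), , drop = FALSE]) - 1) < 1e-9 &
        abs(colSums(tr[c("IM", "II"), , drop = FALSE]) - 1) < 1e-9 &
        abs(colSums(tr[c("DM", "DD"), , drop = FALSE]) - 1) < 1e-9
  if (!all(ok)) stop("transition probabilities must sum to 1 per state", call. = FALSE)
  invisible(hmm)
}

# natural-log parameter matrices for the C++ kernels
hmm_log_params <- function(hmm) {
  mlo <- log(hmm$match_probs) - log(hmm$background)
  mlo[21, ] <- 0
  t7 <- log(hmm$transitions)
  if (hmm$length == 1) t7 <- matrix(numeric(0), 7, 0)
  list(mlo = mlo, t7 = t7, lentry = log(hmm$entry), lexit = log(hmm$exit))
}

#' Viterbi score of a sequence against a profile HMM
#'
#' Best local-alignment path log-odds in bits versus the background null.
#' The aligned path is summarized by the residue interval it covers
#' (0-based half-open).
#'
#' @param hmm a `confeax_hmm`.
#' @param seq residue string or a single sequence record row.
#' @return List with `score_bits`, `start`, `end`.
#' @export
viterbi <- function(hmm, seq) {
  res <- if (is.data.frame(seq)) seq$residues[1] else seq
  codes <- encode_residues(toupper(res))
  p <- hmm_log_params(hmm)
  v <- cpp_viterbi(codes, p$mlo, p$t7, p$lentry, p$lexit)
  list(score_bits = v$score / log(2), start = v$start - 1L, end = v$end)
}

#' Forward score of a sequence against a profile HMM
#'
#' Log-sum over all local paths, in bits; always at least the Viterbi score.
#'
#' @inheritParams viterbi
#' @return Score in bits.
#' @export
forward <- function(hmm, seq) {
  res <- if (is.data.frame(seq)) seq$residues[1] else seq
  codes <- encode_residues(toupper(res))
  p <- hmm_log_params(hmm)
  cpp_forward(codes, p$mlo, p$t7, p$lentry, p$lexit) / log(2)
}

# --- calibration ----------------------------------------------------------

# maximum-likelihood Gumbel fit (location mu, scale 1/lambda)
fit_gumbel <- function(x) {
  if (length(x) < 10 || sd(x) < 1e-9)
    stop("degenerate score distribution: cannot calibrate", call. = FALSE)
  g <- function(lam) {
    e <- exp(-lam * (x - max(x)))
    1 / lam - mean(x) + sum(x * e) / sum(e)
  }
  lam0 <- pi / (sd(x) * sqrt(6))
  lo <- lam0; hi <- lam0
  while (g(lo) < 0 && lo > 1e-8) lo <- lo / 2
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 2
  lam <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  mx <- max(x)
  mu <- mx - log(mean(exp(-lam * (x - mx)))) / lam
  list(mu = mu, lambda = lam)
}

#' Calibrate a profile HMM with an empirical Gumbel null
#'
#' Viterbi scores of `n_random` background-composition random sequences
#' (lengths resampled from `len_dist`) are fitted with a maximum-likelihood
#' Gumbel; E-values are then
#' `E(S) = n_targets * exp(-lambda * (S - mu))`, clipped to
#' `[0, n_targets]`.
#'
#' @param hmm a `confeax_hmm`.
#' @param len_dist integer vector of lengths to resample (e.g. the family's
#'   sequence lengths), or sequence records.
#' @param n_random number of random sequences (at least 100).
#' @param seed RNG seed.
#' @return The HMM with a `calibration` element (`mu`, `lambda`,
#'   `n_random`).
#' @export
calibrate_hmm <- function(hmm, len_dist, n_random = 200, seed = 1) {
  if (n_random < 100) stop("n_random must be >= 100", call. = FALSE)
  if (is.data.frame(len_dist)) len_dist <- nchar(len_dist$residues)
  p <- hmm_log_params(hmm)
  bg20 <- hmm$background[1:20] / sum(hmm$background[1:20])
  scores <- with_seed(seed, {
    lens <- sample(len_dist, n_random, replace = TRUE)
    vapply(lens, function(L) {
      codes <- sample.int(20L, L, replace = TRUE, prob = bg20)
      cpp_viterbi(codes, p$mlo, p$t7, p$lentry, p$lexit)$score / log(2)
    }, 1.0)
  })
  hmm$calibration <- c(fit_gumbel(scores), list(n_random = n_random))
  hmm
}

#' E-value of a bit score under the calibrated null
#'
#' @param hmm a calibrated `confeax_hmm`.
#' @param score_bits bit score(s).
#' @param n_targets number of target sequences searched.
#' @return E-value(s) in `[0, n_targets]`, monotone decreasing in the score.
#' @export
hmm_evalue <- function(hmm, score_bits, n_targets) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("model is not calibrated", call. = FALSE)
  pmin(pmax(n_targets * exp(-cal$lambda * (score_bits - cal$mu)), 0), n_targets)
}

# --- search ---------------------------------------------------------------

#' Search a sequence family with a profile HMM
#'
#' Per sequence, repeatedly takes the best local Viterbi hit, masks its
#' interval, and repeats, until the hit fails the threshold. Thresholds are
#' either permissive E-values (requires calibration) or bit scores. Hits
#' never overlap within a sequence.
#'
#' @param hmm a `confeax_hmm`.
#' @param seqs sequence records.
#' @param threshold `list(evalue = ...)` or `list(bits = ...)`.
#' @param feature_id feature id stamped on the hits.
#' @param iteration iteration index stamped on the hits.
#' @param max_hits_per_seq safety cap on repeats per sequence.
#' @return A feature hit table (0-based half-open), sorted by sequence and
#'   start.
#' @export
hmm_search <- function(hmm, seqs, threshold = list(evalue = 0.01),
                       feature_id = "f1", iteration = 0L,
                       max_hits_per_seq = 25L) {
  use_evalue <- !is.null(threshold$evalue)
  if (use_evalue && is.null(hmm$calibration))
    stop("E-value threshold requires a calibrated model", call. = FALSE)
  p <- hmm_log_params(hmm)
  n_targets <- nrow(seqs)
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    codes <- encode_residues(seqs$residues[i])
    for (h in seq_len(max_hits_per_seq)) {
      v <- cpp_viterbi(codes, p$mlo, p$t7, p$lentry, p$lexit)
      bits <- v$score / log(2)
      if (!is.finite(bits)) break
      ev <- if (is.null(hmm$calibration)) NA_real_
            else hmm_evalue(hmm, bits, n_targets)
      pass <- if (use_evalue) ev <= threshold$evalue else bits >= threshold$bits
      if (!pass) break
      span <- v$start:v$end
      if (all(codes[span] == 21L)) break  # fully masked: nothing new
      out[[length(out) + 1L]] <- data.frame(
        feature_id = feature_id, seq_id = seqs$id[i],
        start = v$start - 1L, end = v$end, score_bits = bits,
        evalue = ev, iteration = as.integer(iteration),
        stringsAsFactors = FALSE)
      codes[span] <- 21L
    }
  }
  hits <- do.call(rbind, out) %||% empty_hits()
  hits[order(hits$seq_id, hits$start), , drop = FALSE]
}

# --- the align -> model -> search iteration ------------------------------

# Jaccard similarity of two hit sets. Exactly identical sets give 1;
# otherwise hits on the same sequence are greedily matched when they overlap
# by at least half of the shorter interval, so boundary jitter of a residue
# or two does not read as a wholesale change of the hit set.
hits_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  keys <- function(h) sprintf("%s:%d-%d", h$seq_id, h$start, h$end)
  if (identical(sort(keys(a)), sort(keys(b)))) return(1)
  matched <- 0L
  for (sid in intersect(unique(a$seq_id), unique(b$seq_id))) {
    ha <- a[a$seq_id == sid, , drop = FALSE]
    hb <- b[b$seq_id == sid, , drop = FALSE]
    used <- logical(nrow(hb))
    for (i in seq_len(nrow(ha))) {
      ok <- which(!used & interval_overlap_ok(ha$start[i], ha$end[i],
                                              hb$start, hb$end))
      if (length(ok)) {
        used[ok[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched / (nrow(a) + nrow(b) - matched)
}

#' Iterate alignment, HMM modelling and search to convergence
#'
#' Starting from a seed motif's hits, repeat: extend hit cores by `flank`
#' residues, align the instances, build and calibrate a profile HMM, and
#' re-search the family. The search reports hits at the permissive
#' `iter_evalue`, but only hits at the stricter `include_evalue` feed the
#' next round's alignment (the usual inclusion/reporting split of iterated
#' homology searches: a threshold permissive enough to capture degenerate
#' sites would otherwise feed expected-false hits into the model and keep
#' it churning). Convergence is judged on the inclusion set: identical to
#' the previous iteration (Jaccard 1, with boundary jitter tolerated via
#' 50%-overlap matching) or Jaccard at least 0.99 for two consecutive
#' iterations; a hard cap of `max_iter` applies.
#'
#' @param seed_motif a `confeax_motif` with at least 2 hits.
#' @param seqs sequence records.
#' @param flank flanking extension per iteration (default 5).
#' @param iter_evalue permissive search/reporting threshold during
#'   iteration.
#' @param include_evalue inclusion threshold: hits entering the next
#'   round's model.
#' @param final_evalue acceptance threshold for `accepted_hits`.
#' @param match_threshold occupancy threshold for HMM match columns.
#' @param n_random calibration sample size per iteration.
#' @param max_iter iteration cap (default 20).
#' @param extend_each_iteration re-apply the flanking extension to the raw
#'   hit cores every round (default) or only once.
#' @param seed RNG seed (calibration randomness).
#' @return List with `hmm` (final calibrated model), `hits` (the converged
#'   hit set at the permissive threshold — the iteration's own result),
#'   `accepted_hits` (`hits` filtered at the stricter `final_evalue`) and
#'   `trace` (per-iteration Jaccard / hit-count records).
#' @export
confeax_iterate <- function(seed_motif, seqs, flank = 5L, iter_evalue = 10,
                            include_evalue = 0.1, final_evalue = 0.01,
                            match_threshold = 0.5, n_random = 200,
                            max_iter = 20L, extend_each_iteration = TRUE,
                            seed = 1) {
  incl <- validate_hits(seed_motif$hits)
  if (nrow(incl) < 2) stop("seed motif needs at least 2 hits", call. = FALSE)
  feature_id <- seed_motif$motif_id %||% "f1"
  trace <- list()
  prev_incl <- incl
  prev2_incl <- NULL
  prev_j <- 0
  hmm <- NULL
  hits <- incl
  for (it in seq_len(max_iter)) {
    ext <- if (extend_each_iteration || it == 1L)
      extend_hits(incl, seqs, flank) else incl
    aln <- align_hits(ext, seqs)
    # background from the whole family, not the instance alignment: the
    # null model must describe the sequences being searched
    hmm <- build_hmm(aln, match_threshold = match_threshold,
                     background = residue_background(seqs))
    # calibration uses the same seed every round, so each iteration is a
    # deterministic map of the inclusion set and an exact fixed point is
    # reachable
    hmm <- calibrate_hmm(hmm, nchar(seqs$residues), n_random = n_random,
                         seed = seed)
    hits <- hmm_search(hmm, seqs, threshold = list(evalue = iter_evalue),
                       feature_id = feature_id, iteration = it)
    incl <- hits[!is.na(hits$evalue) & hits$evalue <= include_evalue, ,
                 drop = FALSE]
    if (nrow(incl) < 2)
      stop("feature lost during iteration (hit set collapsed)", call. = FALSE)
    j <- hits_jaccard(prev_incl, incl)
    # a deterministic map can enter a 2-cycle of borderline hits; when the
    # inclusion set matches the one from two rounds earlier, drop the
    # flickering hits (keep those also present in the previous round)
    if (j < 1 && !is.null(prev2_incl) && hits_jaccard(prev2_incl, incl) == 1) {
      keep <- vapply(seq_len(nrow(incl)), function(i) {
        pb <- prev_incl[prev_incl$seq_id == incl$seq_id[i], , drop = FALSE]
        nrow(pb) > 0 && any(interval_overlap_ok(incl$start[i], incl$end[i],
                                                pb$start, pb$end))
      }, TRUE)
      if (sum(keep) >= 2 && any(!keep)) {
        incl <- incl[keep, , drop = FALSE]
        j <- hits_jaccard(prev_incl, incl)
      }
    }
    converged <- (j == 1) || (j >= 0.99 && prev_j >= 0.99)
    trace[[it]] <- data.frame(iteration = it, jaccard = j,
                              n_hits = nrow(incl), converged = converged)
    if (converged) break
    prev2_incl <- prev_incl
    prev_incl <- incl
    prev_j <- j
  }
  accepted <- hits[!is.na(hits$evalue) & hits$evalue <= final_evalue, , drop = FALSE]
  list(hmm = hmm, hits = hits, accepted_hits = accepted,
       trace = do.call(rbind, trace))
}
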