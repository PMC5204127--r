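default_features <- function() {
  # a MadBub-like feature set: short degenerate motifs and two longer
  # domain-like features; ABBA1/KEN2/ABBA2 form a symmetric cassette that is
  # always co-retained (same retention class)
  data.frame(
    feature_id  = c("KEN1", "DBOX", "ABBA1", "KEN2", "ABBA2", "MADAM",
                    "GLEBS", "CDI", "KARD", "CDII"),
    consensus   = c("DKENGQPL", "RAALSDITN", "FSIFDE", "LKENEGPL", "FEIFDD",
                    "MSNAQRWL", "EWELSKENIQPLRQGRN", "NAFQQSLVE",
                    "STDLSEHTMDGRI", "LDGFEILSPIQ"),
    conservation = c(0.95, 0.8, 0.85, 0.95, 0.85, 0.85, 0.95, 0.85, 0.85, 0.9),
    copies      = 1L,
    prevalence  = 1,
    stringsAsFactors = FALSE)
}

default_retention <- function() {
  c(KEN1 = "MAD", DBOX = "MAD", ABBA1 = "MAD", KEN2 = "MAD", ABBA2 = "MAD",
    MADAM = "MAD", GLEBS = "BUB", CDI = "BUB", KARD = "BUB", CDII = "BUB")
}

#' Configuration for the synthetic gene-family generator
#'
#' Describes a family of homologues across species: some species carry a
#' gene duplication (yielding a MAD and a BUB copy), the rest a single
#' unduplicated MADBUB copy. Each feature is a short consensus planted at a
#' per-column conservation level on i.i.d. background residues; a retention
#' map assigns each feature to one paralogue class (or both) after
#' duplication, `prevalence` thins carriers at random, and `flip_noise`
#' inverts retention bits with a small probability.
#'
#' @param n_species number of species.
#' @param n_duplicated number of species carrying the duplication (first
#'   `n_duplicated` species).
#' @param len_range integer `c(min, max)` sequence length, uniform.
#' @param background 21 background frequencies, or `NULL` for uniform.
#' @param features data frame with columns `feature_id`, `consensus`,
#'   `conservation` (in `[0, 1]`), `copies`, `prevalence`.
#' @param retention named map feature_id -> `"MAD"`, `"BUB"` or `"both"`.
#' @param flip_noise probability in `[0, 0.5)` that a retention bit is
#'   inverted.
#' @return A `confeax_sim_config` list.
#' @export
sim_config <- function(n_species = 24, n_duplicated = 16,
                       len_range = c(300, 1200), background = NULL,
                       features = default_features(),
                       retention = default_retention(),
                       flip_noise = 0) {
  if (is.null(background)) background <- residue_background(uniform = TRUE)
  stopifnot(n_duplicated <= n_species, n_duplicated >= 0,
            flip_noise >= 0, flip_noise < 0.5,
            all(features$conservation >= 0), all(features$conservation <= 1),
            all(nchar(features$consensus) >= 4),
            all(features$feature_id %in% names(retention)),
            all(retention %in% c("MAD", "BUB", "both")))
  structure(list(n_species = n_species, n_duplicated = n_duplicated,
                 len_range = len_range, background = background,
                 features = features, retention = retention,
                 flip_noise = flip_noise),
            class = "confeax_sim_config")
}

#' Preset: planted-motif recovery benchmark
#'
#' 40 unduplicated proteins of length 300 with one fully conserved 10-mer
#' planted in 80% of them — the reference condition for testing de novo
#' discovery.
#' @return A `confeax_sim_config`.
#' @export
sim_config_recovery <- function() {
  sim_config(n_species = 40, n_duplicated = 0, len_range = c(300, 300),
             features = data.frame(feature_id = "MOTIF", consensus = "WIRQDGKHTC",
                                   conservation = 1.0, copies = 1L,
                                   prevalence = 0.8, stringsAsFactors = FALSE),
             retention = c(MOTIF = "both"))
}

#' Preset: degenerate-motif iteration benchmark
#'
#' As [sim_config_recovery()] but the motif has per-column conservation 0.7
#' and only 60% of the proteins carry it — the regime where iterated HMM
#' search should outperform the EM stage alone.
#' @return A `confeax_sim_config`.
#' @export
sim_config_degenerate <- function() {
  sim_config(n_species = 40, n_duplicated = 0, len_range = c(300, 300),
             features = data.frame(feature_id = "MOTIF", consensus = "WIRQDGKHTC",
                                   conservation = 0.7, copies = 1L,
                                   prevalence = 0.6, stringsAsFactors = FALSE),
             retention = c(MOTIF = "both"))
}

#' Preset: subfunctionalization benchmark
#'
#' 16 duplicated species (32 gene copies), the default 10-feature set split
#' into a MAD-retained and a BUB-retained group, with 5% retention flip
#' noise.
#' @param flip_noise probability that a retention bit is inverted.
#' @return A `confeax_sim_config`.
#' @export
sim_config_subfunc <- function(flip_noise = 0.05) {
  sim_config(n_species = 16, n_duplicated = 16, len_range = c(300, 600),
             flip_noise = flip_noise)
}

#' Simulate a gene family with planted features and ground truth
#'
#' Per species, one protein (or a MAD/BUB pair if duplicated). Background
#' residues are i.i.d. from the configured composition; each retained
#' feature is planted at a random non-overlapping position, drawing each
#' column's residue as the consensus letter with probability equal to the
#' conservation and otherwise from the background renormalized over the
#' remaining letters. Deterministic given `seed`.
#'
#' @param config a `confeax_sim_config`.
#' @param seed RNG seed.
#' @return An object of class `confeax_sim`: list with `seqs` (sequence
#'   records), `labels`, and `truth` (planted `sites`, realized `presence`
#'   matrix, `designed` presence matrix, designed feature `bipartition`).
#' @export
simulate_family <- function(config, seed = 1) {
  stopifnot(inherits(config, "confeax_sim_config"))
  bg <- config$background
  bg20 <- bg[1:20] / sum(bg[1:20])
  feats <- config$features
  widths <- nchar(feats$consensus)
  cons_codes <- lapply(feats$consensus, encode_residues)

  with_seed(seed, {
    copies <- list()
    for (s in seq_len(config$n_species)) {
      sp <- sprintf("sp%02d", s)
      if (s <= config$n_duplicated) {
        copies[[length(copies) + 1L]] <- c(id = paste0(sp, "_MAD"),
                                           paralogue = "MAD", species = sp)
        copies[[length(copies) + 1L]] <- c(id = paste0(sp, "_BUB"),
                                           paralogue = "BUB", species = sp)
      } else {
        copies[[length(copies) + 1L]] <- c(id = paste0(sp, "_MB"),
                                           paralogue = "MADBUB", species = sp)
      }
    }
    copies <- as.data.frame(do.call(rbind, copies), stringsAsFactors = FALSE)

    nf <- nrow(feats)
    ncp <- nrow(copies)
    designed <- matrix(0L, ncp, nf, dimnames = list(copies$id, feats$feature_id))
    for (ci in seq_len(ncp)) for (fi in seq_len(nf)) {
      ret <- config$retention[[feats$feature_id[fi]]]
      keep <- ret == "both" || copies$paralogue[ci] == "MADBUB" ||
        copies$paralogue[ci] == ret
      if (keep && runif(1) <= feats$prevalence[fi]) designed[ci, fi] <- 1L
    }
    presence <- designed
    if (config$flip_noise > 0) {
      flips <- matrix(runif(ncp * nf) < config$flip_noise, ncp, nf)
      presence <- matrix(as.integer(xor(designed == 1L, flips)), ncp, nf,
                         dimnames = dimnames(designed))
    }

    sites <- list()
    residues <- character(ncp)
    for (ci in seq_len(ncp)) {
      L <- if (config$len_range[1] == config$len_range[2]) config$len_range[1]
           else sample(config$len_range[1]:config$len_range[2], 1)
      codes <- sample.int(20L, L, replace = TRUE, prob = bg20)
      taken <- logical(L)
      for (fi in seq_len(nf)) {
        if (presence[ci, fi] == 0L) next
        w <- widths[fi]
        for (cp in seq_len(feats$copies[fi])) {
          placed <- FALSE
          for (try in seq_len(500)) {
            st <- sample.int(L - w + 1L, 1)
            span <- st:(st + w - 1L)
            if (!any(taken[span])) {
              c_level <- feats$conservation[fi]
              for (j in seq_len(w)) {
                cc <- cons_codes[[fi]][j]
                if (runif(1) <= c_level) codes[span[j]] <- cc
                else {
                  p <- bg20
                  p[cc] <- 0
                  codes[span[j]] <- sample.int(20L, 1, prob = p / sum(p))
                }
              }
              taken[span] <- TRUE
              sites[[length(sites) + 1L]] <- data.frame(
                seq_id = copies$id[ci], feature_id = feats$feature_id[fi],
                start = st - 1L, end = st - 1L + w, stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("sequence too short for feature load", call. = FALSE)
        }
      }
      residues[ci] <- decode_residues(codes)
    }

    seqs <- seq_records(id = copies$id, residues = residues,
                        paralogue_label = copies$paralogue,
                        clade_label = copies$species)
    labels <- data.frame(id = copies$id, paralogue_label = copies$paralogue,
                         clade_label = copies$species, stringsAsFactors = FALSE)
    bipartition <- ifelse(config$retention == "both", NA_character_,
                          config$retention)
    names(bipartition) <- names(config$retention)
    truth <- list(sites = do.call(rbind, sites) %||%
                    data.frame(seq_id = character(), feature_id = character(),
                               start = integer(), end = integer()),
                  presence = presence, designed = designed,
                  bipartition = bipartition)
    structure(list(seqs = seqs, labels = labels, truth = truth,
                   config = config, seed = seed),
              class = "confeax_sim")
  })
}

#' @export
print.confeax_sim <- function(x, ...) {
  cat(sprintf("Synthetic family: %d proteins (%d duplicated species), %d features, %d planted sites\n",
              nrow(x$seqs), x$config$n_duplicated, nrow(x$config$features),
              nrow(x$truth$sites)))
  invisible(x)
}

# >= 50% overlap of the shorter interval
interval_overlap_ok <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov >= 0.5 * pmin(e1 - s1, e2 - s2)
}

# greedy mapping discovered feature id -> truth feature id by overlap count
map_features <- function(truth_sites, hits) {
  dfeat <- unique(hits$feature_id)
  tfeat <- unique(truth_sites$feature_id)
  counts <- matrix(0L, length(dfeat), length(tfeat),
                   dimnames = list(dfeat, tfeat))
  for (i in seq_len(nrow(hits))) {
    ts <- truth_sites[truth_sites$seq_id == hits$seq_id[i], , drop = FALSE]
    if (!nrow(ts)) next
    ok <- interval_overlap_ok(hits$start[i], hits$end[i], ts$start, ts$end)
    for (f in ts$feature_id[ok]) counts[hits$feature_id[i], f] <-
        counts[hits$feature_id[i], f] + 1L
  }
  out <- character(0)
  while (any(counts > 0)) {
    best <- which(counts == max(counts), arr.ind = TRUE)[1, ]
    out[dfeat[best[1]]] <- tfeat[best[2]]
    counts[best[1], ] <- 0L
    counts[, best[2]] <- 0L
  }
  out
}

#' Score recovery of planted ground truth
#'
#' Site-level precision and recall (a hit is a true positive iff it overlaps
#' a planted site of the mapped feature by at least 50% of the shorter
#' interval), presence-matrix accuracy, and the adjusted Rand index of a
#' feature bipartition against the designed one.
#'
#' @param truth the `truth` element of a [simulate_family()] result.
#' @param hits discovered feature hit table (or `NULL`).
#' @param presence recovered binary presence matrix (or `NULL`).
#' @param feature_clusters named cluster membership of features (or `NULL`).
#' @param feature_map named map discovered id -> truth id; inferred greedily
#'   from overlaps when `NULL`.
#' @return List of metrics; undefined quantities (e.g. precision with no
#'   hits) are `NA`.
#' @export
evaluate_recovery <- function(truth, hits = NULL, presence = NULL,
                              feature_clusters = NULL, feature_map = NULL) {
  out <- list()
  if (!is.null(hits)) {
    hits <- validate_hits(hits)
    ts <- truth$sites
    if (nrow(hits) == 0) {
      out$site_recall <- 0
      out$site_precision <- NA_real_
    } else {
      if (is.null(feature_map)) feature_map <- map_features(ts, hits)
      mapped <- unname(feature_map[hits$feature_id])
      tp_hit <- logical(nrow(hits))
      recovered <- logical(nrow(ts))
      for (i in seq_len(nrow(hits))) {
        if (is.na(mapped[i])) next
        cand <- which(ts$seq_id == hits$seq_id[i] &
                        ts$feature_id == mapped[i])
        if (!length(cand)) next
        ok <- cand[interval_overlap_ok(hits$start[i], hits$end[i],
                                       ts$start[cand], ts$end[cand])]
        if (length(ok)) {
          tp_hit[i] <- TRUE
          recovered[ok] <- TRUE
        }
      }
      out$site_recall <- mean(recovered)
      out$site_precision <- mean(tp_hit)
    }
  }
  if (!is.null(presence)) {
    common_r <- intersect(rownames(presence), rownames(truth$presence))
    common_c <- intersect(colnames(presence), colnames(truth$presence))
    out$presence_accuracy <-
      mean(presence[common_r, common_c] == truth$presence[common_r, common_c])
  }
  if (!is.null(feature_clusters)) {
    bip <- truth$bipartition[names(feature_clusters)]
    keep <- !is.na(bip)
    out$bipartition_ari <-
      mclust::adjustedRandIndex(feature_clusters[keep], bip[keep])
  }
  out
}
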