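#' Discover, refine and profile conserved features of a protein family
#'
#' The full analysis in one call: (1) de novo EM motif discovery with a
#' repeats-allowed site model, (2) per-motif iterative refinement (flank
#' extension, progressive instance alignment, profile-HMM modelling,
#' calibrated permissive search, to convergence), and (3) — when paralogue
#' labels identify duplicated gene copies — binary phylogenetic profiles of
#' the final features, their Pearson coevolution matrix, average-linkage
#' clustering on `d = 1 - r`, and the co-segregation report at the
#' `k`-cluster cut.
#'
#' @param seqs sequence records ([read_fasta()] / [seq_records()]).
#' @param labels optional label table ([read_labels()]); rows with
#'   paralogue label `MAD` or `BUB` are treated as duplicated copies.
#' @param max_motifs,width_range,n_shuffles,sig_threshold passed to
#'   [discover_motifs()].
#' @param iterate run the profile-HMM refinement loop per motif (default
#'   TRUE).
#' @param flank,iter_evalue,final_evalue,max_iter passed to
#'   [confeax_iterate()].
#' @param k clusters for the co-segregation report.
#' @param include_unduplicated also include unduplicated copies as profile
#'   rows (default FALSE: only duplicated copies, the informative ones).
#' @param seed RNG seed; the whole run is deterministic given the seed.
#' @param verbose print stage progress.
#' @return An object of class `confeax` with elements `motifs`, `features`
#'   (per-feature refinement results), `hits` (final accepted hits),
#'   `profiles`, `coevolution` (or NULL without labels), `seed`, `call`.
#' @seealso [simulate_family()] to generate benchmark input,
#'   [run_pipeline()] for the file-in/file-out variant.
#' @export
confeax <- function(seqs, labels = NULL, max_motifs = 10,
                    width_range = c(8, 12), n_shuffles = 20,
                    sig_threshold = 0.05, iterate = TRUE, flank = 5L,
                    iter_evalue = 10, final_evalue = 0.01, max_iter = 20L,
                    k = 2, include_unduplicated = FALSE, seed = 1,
                    verbose = FALSE) {
  cl <- match.call()
  if (!is.null(labels)) seqs <- apply_labels(seqs, labels)
  say <- function(...) if (verbose) message(sprintf(...))

  say("discovering motifs (max %d, widths %d-%d) ...", max_motifs,
      width_range[1], width_range[2])
  motifs <- discover_motifs(seqs, max_motifs = max_motifs,
                            width_range = width_range, seed = seed,
                            n_shuffles = n_shuffles,
                            sig_threshold = sig_threshold, verbose = verbose)
  say("%d motifs accepted", length(motifs))

  features <- list()
  hits_all <- list()
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    if (iterate && nrow(m$hits) >= 2) {
      say("refining %s ...", m$motif_id)
      res <- confeax_iterate(m, seqs, flank = flank,
                             iter_evalue = iter_evalue,
                             final_evalue = final_evalue,
                             max_iter = max_iter, seed = seed + 1000L * i)
      features[[m$motif_id]] <- res
      hits_all[[m$motif_id]] <- res$accepted_hits
    } else {
      features[[m$motif_id]] <- list(hmm = NULL, hits = m$hits, trace = NULL)
      hits_all[[m$motif_id]] <- m$hits
    }
  }
  hits <- do.call(rbind, hits_all) %||% empty_hits()
  rownames(hits) <- NULL

  profiles <- NULL
  coevo <- NULL
  if (!is.null(labels) && length(features)) {
    dup <- seqs[seqs$paralogue_label %in% c("MAD", "BUB") |
                  include_unduplicated, , drop = FALSE]
    if (nrow(dup) >= 2) {
      say("profiling %d features across %d gene copies ...",
          length(features), nrow(dup))
      copies <- data.frame(id = dup$id,
                           paralogue_label = dup$paralogue_label,
                           clade_label = dup$clade_label,
                           stringsAsFactors = FALSE)
      profiles <- build_profiles(hits, copies, names(features))
      n_var <- length(setdiff(names(features), profiles$constant))
      if (n_var >= 2)
        coevo <- coevolution_analysis(profiles, k = min(k, n_var))
    }
  }

  structure(list(motifs = motifs, features = features, hits = hits,
                 profiles = profiles, coevolution = coevo,
                 seqs = seqs, seed = seed, call = cl),
            class = "confeax")
}

#' @export
print.confeax <- function(x, ...) {
  cat("Conserved-feature analysis\n")
  cat(sprintf("  sequences: %d   motifs: %d   accepted hits: %d\n",
              nrow(x$seqs), length(x$motifs), nrow(x$hits)))
  for (m in x$motifs) print(m)
  if (!is.null(x$coevolution)) print(x$coevolution)
  invisible(x)
}

#' @export
summary.confeax <- function(object, ...) {
  per_feat <- do.call(rbind, lapply(names(object$features), function(f) {
    r <- object$features[[f]]
    data.frame(feature_id = f, n_hits = nrow(r$hits),
               iterations = if (is.null(r$trace)) 0L else max(r$trace$iteration),
               converged = if (is.null(r$trace)) NA else any(r$trace$converged),
               stringsAsFactors = FALSE)
  }))
  out <- list(n_seqs = nrow(object$seqs), features = per_feat,
              coevolution = object$coevolution)
  class(out) <- "summary.confeax"
  out
}

#' @export
print.summary.confeax <- function(x, ...) {
  cat(sprintf("confeax summary: %d sequences, %d features\n", x$n_seqs,
              nrow(x$features) %||% 0L))
  if (!is.null(x$features)) print(x$features, row.names = FALSE)
  if (!is.null(x$coevolution)) print(x$coevolution)
  invisible(x)
}

#' Plot a coevolution analysis
#'
#' Feature dendrogram above a presence/absence heatmap of the profile
#' matrix (features in dendrogram order).
#'
#' @param x a `confeax` object with a coevolution component.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.confeax <- function(x, ...) {
  if (is.null(x$coevolution)) {
    warning("no coevolution component to plot", call. = FALSE)
    return(invisible(x))
  }
  dend <- x$coevolution$dendrogram
  m <- x$profiles$matrix[, dend$labels[dend$hclust$order], drop = FALSE]
  op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(dend$hclust, main = "Feature coevolution (UPGMA, d = 1 - r)",
                 xlab = "", sub = "", ylab = "height")
  graphics::par(mar = c(5, 4, 1, 1))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = c("steelblue", "firebrick"), axes = FALSE,
                  xlab = "feature", ylab = "gene copy")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Run the full pipeline on files and write every artifact
#'
#' Reads FASTA (and optional labels TSV), runs [confeax()], and writes:
#' motif models and HMMs (JSON), hits TSV, instance alignments (aligned
#' FASTA + Stockholm), logo TSVs, the profile matrix TSV, correlation and
#' distance TSVs, the dendrogram newick, a report JSON and a run manifest
#' with checksums of every output.
#'
#' @param fasta input FASTA path.
#' @param labels_path optional labels TSV path.
#' @param out_dir output directory (created).
#' @param seed RNG seed.
#' @param ... passed to [confeax()].
#' @return The `confeax` object, invisibly.
#' @export
run_pipeline <- function(fasta, labels_path = NULL, out_dir, seed = 1, ...) {
  seqs <- read_fasta(fasta)
  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path))
      stop("labels file not found: ", labels_path, call. = FALSE)
    labels <- read_labels(labels_path, seqs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- confeax(seqs, labels = labels, seed = seed, ...)

  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  write_hits(fit$hits, emit(file.path(out_dir, "hits.tsv")))
  for (m in fit$motifs)
    write_model_json(m, emit(file.path(out_dir, paste0(m$motif_id, ".motif.json"))))
  for (f in names(fit$features)) {
    r <- fit$features[[f]]
    if (is.null(r$hmm)) next
    write_model_json(r$hmm, emit(file.path(out_dir, paste0(f, ".hmm.json"))))
    if (nrow(r$hits) >= 2) {
      aln <- align_hits(extend_hits(r$hits, fit$seqs), fit$seqs)
      write_fasta(aln$rows, emit(file.path(out_dir, paste0(f, ".aln.fasta"))))
      write_stockholm(aln$rows, emit(file.path(out_dir, paste0(f, ".sto"))))
      write_logo_tsv(logo_matrix(aln), emit(file.path(out_dir, paste0(f, ".logo.tsv"))))
    }
  }
  if (!is.null(fit$profiles))
    write_profile_matrix(fit$profiles, emit(file.path(out_dir, "profiles.tsv")))
  if (!is.null(fit$coevolution)) {
    co <- fit$coevolution
    write.table(round(co$r, 6), emit(file.path(out_dir, "correlation.tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(round(co$d, 6), emit(file.path(out_dir, "distance.tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    writeLines(co$dendrogram$newick, emit(file.path(out_dir, "dendrogram.nwk")))
    jsonlite::write_json(
      list(clusters = as.list(co$clusters),
           enrichment = as.data.frame(co$report$enrichment),
           constant_features = co$constant),
      emit(file.path(out_dir, "report.json")), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    tool = "confeax", version = as.character(utils::packageVersion("confeax")),
    seed = seed,
    inputs = list(fasta = fasta, labels = labels_path),
    parameters = as.list(fit$call)[-1][
      setdiff(names(as.list(fit$call)[-1]), c("seqs", "labels"))],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(fit)
}
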