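#' Extend feature hits by flanking residues
#'
#' Each hit is widened by `flank` residues on both sides (default 5, to
#' compensate for the strict window treatment of the EM stage), clamped to
#' the sequence bounds. Scores are carried over unchanged.
#'
#' @param hits a feature hit table (0-based half-open coordinates).
#' @param seqs sequence records supplying sequence lengths.
#' @param flank residues to add on each side.
#' @return The extended hit table.
#' @export
extend_hits <- function(hits, seqs, flank = 5L) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  len <- stats::setNames(nchar(seqs$residues), seqs$id)
  if (any(!hits$seq_id %in% names(len)))
    stop("hit references unknown sequence id", call. = FALSE)
  L <- len[hits$seq_id]
  hits$start <- pmax(0L, hits$start - as.integer(flank))
  hits$end <- pmin(as.integer(L), hits$end + as.integer(flank))
  hits
}

# extract residue substrings for hits (0-based half-open)
hit_substrings <- function(hits, seqs) {
  res <- stats::setNames(seqs$residues, seqs$id)
  substring(res[hits$seq_id], hits$start + 1L, hits$end)
}

#' Progressive multiple alignment of feature instances
#'
#' All pairwise global alignments (BLOSUM62, affine gap open 11 / extend 1)
#' give pairwise identities; a guide tree is built by average linkage on
#' `1 - identity`; profiles are merged along the tree with the same scoring.
#' Column order preserves the residue order of every instance, so ungapping
#' any row reproduces its input string exactly.
#'
#' @param instances character vector of residue strings (>= 1).
#' @param gap_open,gap_extend affine gap penalties.
#' @return An object of class `confeax_alignment`: list with `rows` (named,
#'   equal-length gapped strings) and `n_cols`.
#' @export
align_instances <- function(instances, gap_open = 11, gap_extend = 1) {
  if (length(instances) == 0) stop("no instances to align", call. = FALSE)
  nm <- names(instances) %||% paste0("i", seq_along(instances))
  nm <- make.unique(nm)
  instances <- toupper(instances)
  if (length(instances) == 1) {
    warning("single instance: trivial alignment", call. = FALSE)
    return(structure(list(rows = stats::setNames(instances, nm),
                          n_cols = nchar(instances)),
                     class = "confeax_alignment"))
  }
  S <- blosum62_matrix()
  enc <- lapply(instances, encode_residues)
  prof1 <- function(codes) {
    m <- matrix(0, 21, length(codes))
    m[cbind(codes, seq_along(codes))] <- 1
    m
  }
  nw <- function(f1, f2) cpp_nw_dp(t(f1) %*% S %*% f2, gap_open, gap_extend)
  n <- length(instances)
  # pairwise identities for the guide tree
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    path <- nw(prof1(enc[[i]]), prof1(enc[[j]]))
    pi1 <- cumsum(path != 2L)
    pi2 <- cumsum(path != 1L)
    mcols <- which(path == 0L)
    ident <- sum(enc[[i]][pi1[mcols]] == enc[[j]][pi2[mcols]]) / length(path)
    d[i, j] <- d[j, i] <- 1 - ident
  }
  guide <- average_linkage_cluster(d)
  # profile-profile merges along the guide tree
  groups <- lapply(seq_len(n), function(i)
    list(rows = stats::setNames(instances[i], nm[i])))
  gap_rows <- function(rows, path, keepcode) {
    vapply(rows, function(r) {
      v <- strsplit(r, "", fixed = TRUE)[[1]]
      out <- character(length(path))
      out[path != keepcode] <- v
      out[path == keepcode] <- "-"
      paste(out, collapse = "")
    }, "")
  }
  profile_of <- function(rows) {
    mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
    f <- apply(mat, 2, function(col) {
      col <- col[col != "-"]
      p <- numeric(21)
      if (length(col)) {
        tb <- table(factor(col, levels = .AA))
        p <- as.numeric(tb) / length(col)
      }
      p
    })
    matrix(f, nrow = 21)
  }
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    pick <- function(ref) if (ref < 0) groups[[-ref]] else merged[[ref]]
    g1 <- pick(guide$merge[step, 1])
    g2 <- pick(guide$merge[step, 2])
    path <- nw(profile_of(g1$rows), profile_of(g2$rows))
    rows <- c(gap_rows(g1$rows, path, 2L), gap_rows(g2$rows, path, 1L))
    merged[[step]] <- list(rows = rows)
  }
  rows <- merged[[n - 1]]$rows[nm]
  structure(list(rows = rows, n_cols = nchar(rows[[1]])),
            class = "confeax_alignment")
}

#' Build an instance alignment from hits
#'
#' Extracts the hit substrings, aligns them with [align_instances()], and
#' records the source coordinates so rows can be traced back.
#'
#' @param hits feature hit table (one feature).
#' @param seqs sequence records.
#' @param ... passed to [align_instances()].
#' @return A `confeax_alignment` with an `instances` data frame attached.
#' @export
align_hits <- function(hits, seqs, ...) {
  hits <- validate_hits(hits)
  subs <- hit_substrings(hits, seqs)
  names(subs) <- sprintf("%s/%d-%d", hits$seq_id, hits$start, hits$end)
  aln <- align_instances(subs, ...)
  aln$instances <- data.frame(seq_id = hits$seq_id, start = hits$start,
                              end = hits$end, row = names(aln$rows),
                              stringsAsFactors = FALSE)
  aln$feature_id <- hits$feature_id[1] %||% NA_character_
  aln
}

#' @export
print.confeax_alignment <- function(x, ...) {
  cat(sprintf("Instance alignment: %d rows x %d columns\n",
              length(x$rows), x$n_cols))
  invisible(x)
}

alignment_char_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

#' Filter alignment columns by occupancy
#'
#' Keeps a column iff its fraction of non-gap characters is at least
#' `min_occupancy` (inclusive at the boundary: 4 residues out of 5 rows pass
#' the default 0.8 threshold). Row order is unchanged.
#'
#' @param aln a `confeax_alignment`.
#' @param min_occupancy fraction in `(0, 1]` (default 0.8).
#' @return The filtered `confeax_alignment`.
#' @export
occupancy_filter <- function(aln, min_occupancy = 0.8) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  m <- alignment_char_matrix(aln)
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  if (!any(keep)) stop("no columns survive occupancy filter", call. = FALSE)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(list(rows = stats::setNames(rows, names(aln$rows)),
                 n_cols = sum(keep), feature_id = aln$feature_id),
            class = "confeax_alignment")
}

#' Sequence-logo matrix of an alignment
#'
#' Per-column letter frequencies over non-gap residues and information
#' content `IC = log2(20) - H` in bits (gaps excluded from counts; an
#' all-gap column has IC 0 and an empty frequency row). IC is clamped to
#' `[0, log2(20)]`.
#'
#' @param aln a `confeax_alignment`.
#' @param pseudocount added to each letter count before normalizing
#'   (default 0, i.e. raw frequencies).
#' @return An object of class `confeax_logo`: list with `freq` (21 x
#'   n_cols), `ic` (bits) and `n` (non-gap count per column).
#' @export
logo_matrix <- function(aln, pseudocount = 0) {
  m <- alignment_char_matrix(aln)
  nc <- ncol(m)
  freq <- matrix(0, 21, nc, dimnames = list(.AA, NULL))
  ic <- numeric(nc)
  n <- integer(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col != "-"]
    n[j] <- length(col)
    if (n[j] == 0) { ic[j] <- 0; next }
    cnt <- as.numeric(table(factor(col, levels = .AA))) + pseudocount
    p <- cnt / sum(cnt)
    freq[, j] <- p
    nz <- p > 0
    h <- -sum(p[nz] * log2(p[nz]))
    ic[j] <- min(max(log2(20) - h, 0), log2(20))
  }
  structure(list(freq = freq, ic = ic, n = n), class = "confeax_logo")
}

#' Write a logo matrix as TSV (column, 21 frequencies, IC, n)
#' @param logo a `confeax_logo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(column = seq_along(logo$ic) - 1L, t(logo$freq),
                   ic_bits = logo$ic, n = logo$n, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
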