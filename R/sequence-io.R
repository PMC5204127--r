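#' Construct a sequence record table
#'
#' The in-memory representation of a protein family: one row per sequence
#' with columns `id`, `description`, `residues`, `paralogue_label`,
#' `clade_label`. Residues are uppercase over the 21-letter alphabet
#' (see [confeax_alphabet()]).
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of residue strings.
#' @param description optional free text per sequence.
#' @param paralogue_label,clade_label optional per-sequence labels (e.g.
#'   `"MAD"`, `"BUB"`, `"MADBUB"`; a clade name).
#' @return A `data.frame` of sequence records.
#' @export
seq_records <- function(id, residues, description = "",
                        paralogue_label = NA_character_,
                        clade_label = NA_character_) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  for (i in seq_along(id)) {
    if (!nzchar(residues[i]))
      stop(sprintf("sequence '%s' is empty", id[i]), call. = FALSE)
    off <- first_illegal_offset(residues[i])
    if (!is.na(off))
      stop(sprintf("sequence '%s': illegal residue at offset %d", id[i], off),
           call. = FALSE)
  }
  data.frame(id = id, description = rep_len(as.character(description), length(id)),
             residues = residues,
             paralogue_label = rep_len(as.character(paralogue_label), length(id)),
             clade_label = rep_len(as.character(clade_label), length(id)),
             stringsAsFactors = FALSE)
}

# shared FASTA text parser; validation is the caller's job
parse_fasta_lines <- function(path) {
  lines <- readLines(path)
  hdr_at <- grep("^>", lines)
  if (length(hdr_at) == 0) stop("no sequences in '", path, "'", call. = FALSE)
  ends <- c(hdr_at[-1] - 1L, length(lines))
  hdr <- sub("^>", "", lines[hdr_at])
  res <- vapply(seq_along(hdr_at), function(i) {
    if (ends[i] < hdr_at[i] + 1L) return("")
    paste(trimws(lines[(hdr_at[i] + 1L):ends[i]]), collapse = "")
  }, "")
  list(id = sub("\\s.*$", "", hdr),
       description = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
       residues = toupper(res))
}

#' Read protein sequences from a FASTA file
#'
#' Residues are uppercased; order is preserved; duplicate ids and characters
#' outside the 21-letter alphabet are rejected (the error names the sequence
#' and the 0-based offset of the first illegal character).
#'
#' @param path path to a FASTA file.
#' @return A sequence record `data.frame` (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  p <- parse_fasta_lines(path)
  seq_records(id = p$id, residues = p$residues, description = p$description)
}

#' Write sequences to FASTA
#'
#' @param seqs sequence record data frame, or a named character vector of
#'   residue strings (gaps allowed, for alignments).
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.data.frame(seqs)) {
    ids <- ifelse(nzchar(seqs$description %||% ""),
                  paste(seqs$id, seqs$description), seqs$id)
    res <- seqs$residues
  } else {
    ids <- names(seqs)
    res <- unname(seqs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(res)) {
    writeLines(paste0(">", ids[i]), con)
    s <- res[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Read an aligned FASTA ("-"/"." gaps allowed; "." normalized to "-")
read_alignment_fasta <- function(path) {
  p <- parse_fasta_lines(path)
  rows <- gsub(".", "-", p$residues, fixed = TRUE)
  names(rows) <- p$id
  for (i in seq_along(rows)) {
    off <- first_illegal_offset(rows[i], allow_gaps = TRUE)
    if (!is.na(off))
      stop(sprintf("alignment row '%s': illegal character at offset %d",
                   names(rows)[i], off), call. = FALSE)
  }
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows differ in length", call. = FALSE)
  rows
}

#' Write an alignment in Stockholm format
#'
#' Minimal Stockholm 1.0 writer: one `name  row` line per sequence. On
#' reading, "." (insert-column gap) and "-" are both accepted and
#' normalized to "-".
#'
#' @param rows named character vector of equal-length aligned strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(rows, path) {
  stopifnot(length(unique(nchar(rows))) == 1)
  nm <- names(rows)
  if (is.null(nm)) nm <- paste0("row", seq_along(rows))
  pad <- formatC(nm, width = max(nchar(nm)), flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(paste(pad, unname(rows)), con)
  writeLines("//", con)
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' @param path path to a Stockholm 1.0 file.
#' @return Named character vector of aligned rows (gaps as `-`).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) stop("no alignment rows in '", path, "'", call. = FALSE)
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  rows <- toupper(trimws(sub("^\\S+\\s+", "", lines)))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  # sequences may be split over multiple blocks: concatenate per name
  agg <- tapply(rows, factor(parts, levels = unique(parts)), paste0, collapse = "")
  out <- as.character(agg)
  names(out) <- names(agg)
  if (length(unique(nchar(out))) != 1)
    stop("alignment rows differ in length", call. = FALSE)
  out
}

#' Read per-sequence labels from a TSV sidecar
#'
#' Two or three tab-separated columns: id, paralogue label, and optionally a
#' clade label. Ids absent from `seqs` (when given) produce warnings, not
#' errors, and are retained.
#'
#' @param path TSV path.
#' @param seqs optional sequence records used to flag unknown ids.
#' @param header logical; does the file carry a header line?
#' @return `data.frame` with columns `id`, `paralogue_label`, `clade_label`.
#' @export
read_labels <- function(path, seqs = NULL, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(id = character(), paralogue_label = character(),
                      clade_label = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, 1L)
  bad <- which(n < 2 | n > 3)
  if (length(bad))
    stop(sprintf("malformed label row at line %d (expected 2-3 columns, got %d)",
                 bad[1] + as.integer(header), n[bad[1]]), call. = FALSE)
  out <- data.frame(
    id = vapply(parts, `[`, "", 1L),
    paralogue_label = vapply(parts, `[`, "", 2L),
    clade_label = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
    stringsAsFactors = FALSE)
  if (!is.null(seqs)) {
    unknown <- setdiff(out$id, seqs$id)
    if (length(unknown))
      warning("label ids not in sequence set: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

# attach labels to sequence records
apply_labels <- function(seqs, labels) {
  i <- match(seqs$id, labels$id)
  seqs$paralogue_label <- ifelse(is.na(i), seqs$paralogue_label, labels$paralogue_label[i])
  seqs$clade_label <- ifelse(is.na(i), seqs$clade_label, labels$clade_label[i])
  seqs
}

.HIT_COLS <- c("feature_id", "seq_id", "start", "end", "score_bits",
               "evalue", "iteration")

# empty feature-hit table; coordinates are 0-based half-open throughout
empty_hits <- function() {
  data.frame(feature_id = character(), seq_id = character(),
             start = integer(), end = integer(), score_bits = numeric(),
             evalue = numeric(), iteration = integer(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  miss <- setdiff(.HIT_COLS, names(hits))
  if (length(miss))
    stop("hit table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(hits)) {
    if (any(hits$start < 0)) stop("negative hit start", call. = FALSE)
    if (any(hits$end <= hits$start))
      stop("hit end must exceed start (0-based half-open)", call. = FALSE)
    if (any(!is.finite(hits$score_bits)))
      stop("non-finite hit score", call. = FALSE)
  }
  hits[, .HIT_COLS]
}

#' Write / read feature hit tables
#'
#' Tab-separated with header `feature_id seq_id start end score_bits evalue
#' iteration`; coordinates 0-based half-open. Reading and writing are mutual
#' inverses.
#'
#' @param hits a hit table (`data.frame`).
#' @param path TSV path.
#' @return `write_hits`: `path` invisibly; `read_hits`: the hit table.
#' @export
write_hits <- function(hits, path) {
  hits <- validate_hits(hits)
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty_hits())
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$iteration <- as.integer(df$iteration)
  validate_hits(df)
}

#' Write / read a binary feature profile matrix as TSV
#'
#' Rows are gene copies (with their labels), columns are features.
#'
#' @param profiles a profile object from [build_profiles()].
#' @param path TSV path.
#' @return `write_profile_matrix`: `path` invisibly; `read_profile_matrix`:
#'   a profile object.
#' @export
write_profile_matrix <- function(profiles, path) {
  m <- profiles$matrix
  df <- data.frame(copy_id = rownames(m),
                   paralogue_label = profiles$copies$paralogue_label,
                   clade_label = profiles$copies$clade_label,
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(m) <- df$copy_id
  storage.mode(m) <- "integer"
  structure(list(matrix = m,
                 copies = data.frame(id = df$copy_id,
                                     paralogue_label = df$paralogue_label,
                                     clade_label = df$clade_label,
                                     stringsAsFactors = FALSE),
                 constant = colnames(m)[apply(m, 2, function(x) length(unique(x)) == 1)]),
            class = "confeax_profiles")
}

#' Serialize a motif or HMM model to JSON
#'
#' Full-precision, deterministic JSON; [read_model_json()] restores the
#' object.
#'
#' @param model a `confeax_motif` or `confeax_hmm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  type <- if (inherits(model, "confeax_hmm")) "hmm" else "motif"
  payload <- list(schema = "confeax-model/1", type = type,
                  model = unclass_deep(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    return(x)
  }
  if (is.matrix(x))
    return(list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
                data = as.numeric(x)))
  x
}

reclass_deep <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
      if (!is.null(x$dimnames))
        dimnames(m) <- lapply(x$dimnames, function(d) if (length(d)) unlist(d) else NULL)
      return(m)
    }
    return(lapply(x, reclass_deep))
  }
  x
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "confeax-model/1"))
    stop("unrecognized model JSON schema", call. = FALSE)
  model <- reclass_deep(payload$model)
  if (identical(payload$type, "hmm")) {
    model$background <- stats::setNames(unlist(model$background), .AA)
    class(model) <- "confeax_hmm"
  } else {
    if (!is.null(model$pwm)) {
      model$pwm$background <- stats::setNames(unlist(model$pwm$background), .AA)
      class(model$pwm) <- "confeax_pwm"
    }
    if (!is.null(model$hits)) {
      h <- as.data.frame(lapply(.HIT_COLS, function(cn)
        unlist(lapply(model$hits, function(r) r[[cn]] %||% NA))),
        stringsAsFactors = FALSE)
      names(h) <- .HIT_COLS
      model$hits <- if (length(model$hits)) h else empty_hits()
    }
    class(model) <- "confeax_motif"
  }
  model
}
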