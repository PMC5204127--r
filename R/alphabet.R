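#' The residue alphabet
#'
#' 20 canonical amino acids plus `X` (unknown). `X` emits the background
#' frequency in every scoring context, i.e. contributes zero log-odds.
#'
#' @return Character vector of 21 single-letter residue codes.
#' @export
confeax_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y", "X")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
         "R", "S", "T", "V", "W", "Y", "X")
.AA_CODE <- stats::setNames(seq_along(.AA), .AA)

# residue string -> integer codes 1..21; gaps are not allowed here
encode_residues <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- .AA_CODE[v]
  if (anyNA(code)) {
    off <- which(is.na(code))[1L]
    stop(sprintf("illegal residue '%s' at offset %d", v[off], off - 1L),
         call. = FALSE)
  }
  unname(code)
}

decode_residues <- function(code) paste(.AA[code], collapse = "")

# first illegal character's 0-based offset, or NA if clean
first_illegal_offset <- function(x, allow_gaps = FALSE) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  ok <- v %in% .AA
  if (allow_gaps) ok <- ok | v %in% c("-", ".")
  if (all(ok)) NA_integer_ else which(!ok)[1L] - 1L
}

#' Background residue frequencies
#'
#' Letter frequencies of a sequence set over the 21-letter alphabet, with one
#' pseudo-observation per letter so every frequency is strictly positive.
#' With `uniform = TRUE` the 20 canonical letters get equal mass and `X` a
#' small floor.
#'
#' @param seqs a sequence record data frame (see [read_fasta()]) or a
#'   character vector of residue strings.
#' @param uniform logical; ignore composition and return the uniform
#'   background.
#' @return Named numeric vector of 21 frequencies summing to 1.
#' @export
residue_background <- function(seqs = NULL, uniform = FALSE) {
  if (uniform || is.null(seqs)) {
    bgx <- 1e-4
    bg <- c(rep((1 - bgx) / 20, 20), bgx)
    names(bg) <- .AA
    return(bg)
  }
  res <- if (is.data.frame(seqs)) seqs$residues else seqs
  tab <- table(factor(unlist(strsplit(res, "", fixed = TRUE)), levels = .AA))
  counts <- as.numeric(tab) + 1
  bg <- counts / sum(counts)
  names(bg) <- .AA
  bg
}

# BLOSUM62 restricted to the 21-letter alphabet, cached after first use
.blosum_cache <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62[.AA, .AA]
  }
  .blosum_cache$m
}
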