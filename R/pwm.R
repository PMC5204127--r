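#' Position weight matrix constructor
#'
#' A PWM over the 21-letter alphabet: `width` columns of letter
#' probabilities, a background distribution, and the pseudocount used at
#' estimation. Every column sums to 1; the `X` row always equals the
#' background `X` frequency, so `X` scores zero log-odds.
#'
#' @param probs 21 x width numeric matrix of column probabilities (rows named
#'   by [confeax_alphabet()]).
#' @param background 21 background frequencies summing to 1.
#' @param pseudocount pseudocount used when the matrix was estimated.
#' @return An object of class `confeax_pwm`.
#' @export
new_pwm <- function(probs, background, pseudocount = 0.01) {
  stopifnot(is.matrix(probs), nrow(probs) == 21)
  rownames(probs) <- .AA
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1", call. = FALSE)
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM columns must sum to 1", call. = FALSE)
  if (any(probs <= 0))
    stop("PWM entries must be strictly positive", call. = FALSE)
  structure(list(width = ncol(probs), probs = probs,
                 background = stats::setNames(as.numeric(background), .AA),
                 pseudocount = pseudocount),
            class = "confeax_pwm")
}

# PWM from posterior-weighted counts: canonical letters get
# (count + pseudocount) renormalized to 1 - bg[X]; X observations carry no
# emission information and the X row is pinned at bg[X].
pwm_from_counts <- function(counts, background, pseudocount = 0.01) {
  w <- ncol(counts)
  bgx <- background[21]
  probs <- matrix(0, 21, w, dimnames = list(.AA, NULL))
  num <- counts[1:20, , drop = FALSE] + pseudocount
  probs[1:20, ] <- sweep(num, 2, colSums(num), "/") * (1 - bgx)
  probs[21, ] <- bgx
  new_pwm(probs, background, pseudocount)
}

# PWM for a single seed window: 0.7 on the observed letter, remainder spread
# uniformly over the other 19 canonical letters (deterministic seeding)
seed_pwm <- function(window_codes, background) {
  w <- length(window_codes)
  bgx <- background[21]
  probs <- matrix(0.3 / 19 * (1 - bgx), 21, w, dimnames = list(.AA, NULL))
  for (j in seq_len(w)) probs[window_codes[j], j] <- 0.7 * (1 - bgx)
  probs[21, ] <- bgx
  new_pwm(probs, background)
}

# natural-log p/bg ratios for the C++ kernels; X row exactly 0
pwm_logratio <- function(pwm) {
  lr <- log(pwm$probs) - log(pwm$background)
  lr[21, ] <- 0
  lr
}

#' Log-odds score of a window against a PWM
#'
#' `sum_j log2(p[j, a_j] / bg[a_j])` in bits; `X` positions contribute 0.
#'
#' @param pwm a `confeax_pwm`.
#' @param window residue string of length `pwm$width`.
#' @return Score in bits.
#' @export
score_window <- function(pwm, window) {
  codes <- encode_residues(toupper(window))
  if (length(codes) != pwm$width)
    stop(sprintf("window length %d does not match PWM width %d",
                 length(codes), pwm$width), call. = FALSE)
  lr <- pwm_logratio(pwm) / log(2)
  sum(lr[cbind(codes, seq_along(codes))])
}

#' @export
print.confeax_pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix: width %d, consensus %s\n",
              x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (most probable letter per column)
#' @param pwm a `confeax_pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(.AA[apply(pwm$probs[1:20, , drop = FALSE], 2, which.max)],
        collapse = "")
}
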