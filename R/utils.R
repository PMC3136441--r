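# Low-level string helpers shared by the simulator and the analyzer.
# All coordinates are 0-based half-open unless a function says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a 0-based half-open substring
#' @noRd
s0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the alphabet A/C/G/T (uppercase).
#' @return The reverse complement, as a character scalar.
#' @examples
#' revcomp("GGTTAG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- chartr("ACGT", "TGCA", x)
  paste(rev(strsplit(ch, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Random DNA with a target GC content
#' @noRd
random_dna <- function(n, gc = 0.48) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Apply uniform random substitutions to a sequence
#'
#' Substitution-only mutation model: each base is replaced, independently
#' with probability `rate`, by one of the three other bases.  Used both for
#' the divergence of captured telomeric/subtelomeric blocks and as the
#' read-noise model.
#'
#' @param seq DNA string (uppercase A/C/G/T).
#' @param rate Per-base substitution probability.
#' @param seed Integer seed; the call is deterministic given `(seq, rate, seed)`.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nchar(seq) == 0L) return(seq)
  withr::with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste(ch, collapse = "")
  })
}

# Longest common prefix length of ref[a..] and ref[b..] style comparisons,
# expressed on two explicit strings; capped so engineered searches stay O(1).
lcp_len <- function(x, y, cap = 30L) {
  n <- min(nchar(x), nchar(y), cap)
  if (n == 0L) return(0L)
  cx <- strsplit(substr(x, 1L, n), "", fixed = TRUE)[[1]]
  cy <- strsplit(substr(y, 1L, n), "", fixed = TRUE)[[1]]
  neq <- which(cx != cy)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Longest common suffix length of two strings, capped.
lcs_len <- function(x, y, cap = 30L) {
  n <- min(nchar(x), nchar(y), cap)
  if (n == 0L) return(0L)
  cx <- strsplit(substr(x, nchar(x) - n + 1L, nchar(x)), "", fixed = TRUE)[[1]]
  cy <- strsplit(substr(y, nchar(y) - n + 1L, nchar(y)), "", fixed = TRUE)[[1]]
  neq <- which(rev(cx) != rev(cy))
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Validate an uppercase DNA string, reporting the first offending offset
# (0-based) in the error message.
check_dna <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)[1]
  if (bad > 0) {
    stop(sprintf("non-ACGT character '%s' in %s at offset %d",
                 substr(seq, bad, bad), what, bad - 1L), call. = FALSE)
  }
  invisible(TRUE)
}
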