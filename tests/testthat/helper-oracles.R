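# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive re-derivations (character loops, exhaustive scans) and
# never call into the package's optimized paths.

shared_env <- new.env(parent = emptyenv())

shared_ref <- function() {
  if (is.null(shared_env$ref)) shared_env$ref <- build_reference(seed = 1L)
  shared_env$ref
}

MECHS <- c("telomere_healing", "telomere_capture", "ring_junction",
           "translocation", "nhej_interstitial", "fostes_mmbir")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# exhaustive bidirectional extension at known breakpoints:
# prefix match of seqA from a (0-based) against seqB from b, plus suffix
# match of seqA before a against seqB before b
oracle_mh <- function(seqA, a, seqB, b) {
  ca <- chars(seqA); cb <- chars(seqB)
  right <- 0L
  while (a + right < length(ca) && b + right < length(cb) &&
         ca[a + right + 1L] == cb[b + right + 1L]) right <- right + 1L
  left <- 0L
  while (a - left >= 1L && b - left >= 1L &&
         ca[a - left] == cb[b - left]) left <- left + 1L
  left + right
}

# k-loop fusion-microhomology oracle: largest k with the reference suffix
# equal to the length-k suffix of GGTTAG
oracle_fusion_mh <- function(ref_suffix) {
  n <- nchar(ref_suffix)
  for (k in 6:1) {
    if (k <= n &&
        substr(ref_suffix, n - k + 1L, n) ==
          substr("GGTTAG", 7L - k, 6L)) return(k)
  }
  0L
}

# exhaustive 6-phase telomere-array scan: longest run of consecutive
# 6-mers each within Hamming distance 1 of GGTTAG, single phase
oracle_telomere_scan <- function(seq, min_copies = 3L) {
  n <- nchar(seq)
  if (n < 6L) return(NULL)
  unit <- chars("GGTTAG")
  ch <- chars(seq)
  best <- NULL
  for (start in 0:(n - 6L)) {
    copies <- 0L
    s <- start
    while (s + 6L <= n &&
           sum(ch[(s + 1L):(s + 6L)] != unit) <= 1L) {
      copies <- copies + 1L
      s <- s + 6L
    }
    if (copies >= min_copies &&
        (is.null(best) || copies > best$copies)) {
      best <- list(start = start, copies = copies)
    }
  }
  best
}

# brute-force palindrome scan: every (arm start, arm length, loop) triple
oracle_palindrome_exists <- function(seq, min_arm = 5L, max_loop = 10L) {
  n <- nchar(seq)
  ch <- chars(seq)
  comp <- chars(chartr("ACGT", "TGCA", seq))
  for (i in seq_len(n)) {            # 1-based last base of left arm
    for (loop in 0:max_loop) {
      j <- i + loop + 1L             # first base of right arm
      l <- 0L
      while (i - l >= 1L && j + l <= n && ch[i - l] == comp[j + l]) l <- l + 1L
      if (l >= min_arm) return(TRUE)
    }
  }
  FALSE
}

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}
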