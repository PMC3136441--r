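# Telomere hexamer-array detection and fusion-point microhomology.
#
# Arrays are runs of consecutive 6-mers, in a single phase, each within
# Hamming distance 1 of the canonical G-rich unit GGTTAG.  Distance-1
# tolerance captures the variant units seen at real healed breakpoints
# (GGTGAG, GGTCAG); distance-2 units break the run.  Scanning is
# strand-specific: only the G-rich strand is considered.

TELOMERE_UNIT <- "GGTTAG"

#' Find the longest telomere hexamer array in a sequence
#'
#' Scans all six phases for the longest run of consecutive 6-mers each
#' within Hamming distance 1 of GGTTAG.  A run qualifies when it has at
#' least `min_copies` units; the `canonical` flag records whether the
#' canonical fraction reaches `1 - max_variant_fraction` (an array of pure
#' variant units is reported but flagged, and downstream classification
#' does not count it as telomere healing).
#'
#' @param seq Uppercase DNA string; non-ACGT characters are an error naming
#'   the (0-based) offset.
#' @param min_copies Minimum number of units (default 3).
#' @param max_variant_fraction Maximum tolerated fraction of variant units
#'   for the array to count as canonical.
#' @return `NULL` if no qualifying run, else a `telomere_array_hit`:
#'   `start`/`end` (0-based half-open query positions, `end - start` =
#'   `6 * copies`), `copies`, `canonical_copies`, `variant_units`
#'   (data.frame of `offset`, `unit`), `phase` (`start %% 6`), `canonical`.
#' @examples
#' find_telomere_array(paste0(strrep("A", 30), strrep("GGTTAG", 6)))
#' @export
find_telomere_array <- function(seq, min_copies = 3L,
                                max_variant_fraction = 0.5) {
  stopifnot(is.character(seq), length(seq) == 1L, min_copies >= 1L)
  check_dna(seq)
  n <- nchar(seq)
  if (n < 6L * min_copies) return(NULL)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  unit <- strsplit(TELOMERE_UNIT, "", fixed = TRUE)[[1]]
  m <- n - 5L
  d <- integer(m)
  for (j in 1:6) d <- d + (ch[j:(m + j - 1L)] != unit[j])
  ok <- d <= 1L

  best <- NULL
  for (ph in 0:5) {
    idx <- seq.int(ph + 1L, m, by = 6L)
    if (length(idx) == 0L) next
    r <- rle(ok[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_copies)
    for (k in runs) {
      copies <- r$lengths[k]
      start <- idx[starts[k]] - 1L     # 0-based
      if (is.null(best) || copies > best$copies ||
          (copies == best$copies && start < best$start)) {
        best <- list(start = start, copies = copies)
      }
    }
  }
  if (is.null(best)) return(NULL)
  offs <- best$start + 6L * (seq_len(best$copies) - 1L)
  units <- substring(seq, offs + 1L, offs + 6L)
  is_var <- units != TELOMERE_UNIT
  hit <- list(start = best$start, end = best$start + 6L * best$copies,
              copies = as.integer(best$copies),
              canonical_copies = as.integer(sum(!is_var)),
              variant_units = data.frame(offset = offs[is_var],
                                         unit = units[is_var],
                                         stringsAsFactors = FALSE),
              phase = best$start %% 6L,
              canonical = mean(!is_var) >= 1 - max_variant_fraction)
  class(hit) <- "telomere_array_hit"
  hit
}

#' @export
print.telomere_array_hit <- function(x, ...) {
  cat(sprintf("telomere array: [%d,%d) %d copies (%d canonical)%s\n",
              x$start, x$end, x$copies, x$canonical_copies,
              if (x$canonical) "" else " [non-canonical]"))
  invisible(x)
}

#' Fusion-point microhomology with the canonical telomere repeat
#'
#' Returns the largest `k` (0-6) such that the last `k` bases of the
#' reference suffix immediately left of the fusion equal the `k` bases a
#' canonical in-phase telomere extension would place immediately before the
#' array's first unit, i.e. the length-`k` suffix of GGTTAG.  Computed by
#' brute force over `k = 6..0`.
#'
#' @param proximal_ref_suffix Reference sequence immediately left of the
#'   fusion point (at least 6 bp).
#' @param array A `telomere_array_hit` (its phase must be defined).
#' @return Integer in 0..6.
#' @examples
#' arr <- find_telomere_array(strrep("GGTTAG", 4))
#' telomere_fusion_microhomology("ACACCCTTAG", arr)  # TTAG -> 4
#' @export
telomere_fusion_microhomology <- function(proximal_ref_suffix, array) {
  stopifnot(is.character(proximal_ref_suffix), length(proximal_ref_suffix) == 1L)
  if (nchar(proximal_ref_suffix) < 6L) {
    stop("proximal_ref_suffix must be at least 6 bp", call. = FALSE)
  }
  if (is.null(array$phase) || is.na(array$phase)) {
    stop("array phase undefined", call. = FALSE)
  }
  check_dna(proximal_ref_suffix, "proximal_ref_suffix")
  n <- nchar(proximal_ref_suffix)
  for (k in 6:1) {
    if (substr(proximal_ref_suffix, n - k + 1L, n) == hex_suffix(k)) {
      return(as.integer(k))
    }
  }
  0L
}

#' Find inverted palindromes (hairpin arms) in a sequence
#'
#' Reports maximal arms whose reverse complement matches across a loop of
#' at most `max_loop` bases.  Overlapping reports are suppressed to the
#' longest arm (ties to the leftmost).
#'
#' @param seq Uppercase DNA string.
#' @param min_arm Minimum arm length.
#' @param max_loop Maximum loop length (0 = perfect palindrome allowed).
#' @return data.frame with `arm_start` (0-based start of the left arm),
#'   `arm_len`, `loop_len`; zero rows when nothing qualifies.
#' @export
find_inverted_palindrome <- function(seq, min_arm = 5L, max_loop = 10L) {
  check_dna(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", ch)
  hits <- list()
  # loop spans [a, a + loop) 0-based; arms extend outward from it
  for (loop in 0:max_loop) {
    for (a in seq_len(n - loop + 1L) - 1L) {
      i <- a          # next left-arm base is ch[i] (0-based i-1..)
      j <- a + loop   # next right-arm base is ch[j+1]
      l <- 0L
      while (i - l - 1L >= 0L && j + l < n &&
             ch[i - l] == comp[j + l + 1L]) {
        l <- l + 1L
      }
      if (l >= min_arm) {
        # maximality across loop placements: skip if extendable by shifting
        hits[[length(hits) + 1L]] <-
          c(arm_start = i - l, arm_len = l, loop_len = loop)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(arm_start = integer(), arm_len = integer(),
                      loop_len = integer()))
  }
  h <- unique(as.data.frame(do.call(rbind, hits)))
  # suppress overlapping reports, keeping the longest arm (then leftmost)
  h <- h[order(-h$arm_len, h$arm_start, h$loop_len), ]
  span_s <- h$arm_start
  span_e <- h$arm_start + 2L * h$arm_len + h$loop_len
  keep <- logical(nrow(h))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(h))) {
    if (!any(span_s[i] < occ_e & span_e[i] > occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, span_s[i]); occ_e <- c(occ_e, span_e[i])
    }
  }
  h <- h[keep, ]
  h[order(h$arm_start), , drop = FALSE]
}
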