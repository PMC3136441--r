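# Array-CGH arm: forward simulation of probe-level log2-ratio profiles,
# derivative-log-ratio QC, binary segmentation and mosaic-fraction
# estimation for stepped mosaic terminal deletions.
#
# The copy-number mixture model is deletion-only: a heterozygous single-copy
# loss carried by a fraction f of cells gives an expected probe ratio of
# log2((2 - f) / 2), so f = 0 -> 0, f = 1 -> -1.  Fractions are recovered
# by inverting this forward model.

#' Simulate a probe-level aCGH log2-ratio profile
#'
#' Each segment contributes `length_bp / spacing` probes whose expected
#' ratio is `log2((2 - f) / 2)` for its deleted-cell fraction `f`, plus
#' i.i.d. Gaussian noise.
#'
#' @param segments data.frame (or list coercible to one) with columns
#'   `length_bp` and `fraction` (deleted-cell fraction in `[0, 1]`).
#' @param spacing Probe spacing in bp (default 400, the average resolution
#'   of a high-density custom array).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return data.frame of class `acgh_profile`: `position` (bp, strictly
#'   increasing), `log2_ratio`; attribute `truth` holds the generating
#'   segment table with probe-index boundaries.
#' @export
simulate_profile <- function(segments, spacing = 400L, noise_sd = 0.1,
                             seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("length_bp", "fraction") %in% names(segments)),
            all(segments$fraction >= 0), all(segments$fraction <= 1),
            all(segments$length_bp > 0), spacing > 0)
  n_probes <- pmax(1L, as.integer(round(segments$length_bp / spacing)))
  mu <- log2((2 - segments$fraction) / 2)
  expected <- rep(mu, n_probes)
  withr::with_seed(seed, {
    lr <- expected + rnorm(length(expected), sd = noise_sd)
  })
  pos <- as.integer(seq_along(expected)) * spacing - spacing %/% 2L
  prof <- data.frame(position = pos, log2_ratio = lr)
  class(prof) <- c("acgh_profile", "data.frame")
  ends <- cumsum(n_probes)
  attr(prof, "truth") <- data.frame(
    start_idx = c(0L, head(ends, -1L)), end_idx = ends,
    fraction = segments$fraction, mean_log2 = mu)
  attr(prof, "spacing") <- as.integer(spacing)
  prof
}

#' Derivative log-ratio spread of a profile
#'
#' Robust probe-to-probe noise metric:
#' `IQR(consecutive differences) / (1.349 * sqrt(2))`.  For i.i.d. Gaussian
#' probe noise this estimates the per-probe standard deviation.
#'
#' @param profile An `acgh_profile` (or any data.frame with `log2_ratio`).
#' @return Non-negative numeric scalar.
#' @export
dlr_spread <- function(profile) {
  x <- profile$log2_ratio
  if (length(x) < 3L) stop("too few probes", call. = FALSE)
  IQR(diff(x)) / (1.349 * sqrt(2))
}

#' Quality-control gate on the DLR spread
#'
#' Profiles pass when `dlr_spread(profile) < threshold`; 0.30 is the
#' conventional ceiling for interpretable experiments.
#'
#' @inheritParams dlr_spread
#' @param threshold DLR ceiling.
#' @return Logical scalar.
#' @export
qc_pass <- function(profile, threshold = 0.30) {
  dlr_spread(profile) < threshold
}

#' Estimate the deleted-cell fraction from a segment mean
#'
#' Exact inverse of the single-copy-loss mixture forward model:
#' `f = 2 * (1 - 2^L)`, clipped to `[0, 1]`.
#'
#' @param mean_log2 Segment mean log2 ratio (numeric vector allowed).
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' estimate_fraction(0)    # 0
#' estimate_fraction(-1)   # 1
#' estimate_fraction(-0.3) # 0.3755
#' @export
estimate_fraction <- function(mean_log2) {
  pmin(1, pmax(0, 2 * (1 - 2^mean_log2)))
}

#' Segment a profile by binary segmentation on means
#'
#' Recursive binary segmentation: each candidate split maximizes the
#' reduction in residual sum of squares and is accepted when the reduction
#' exceeds `penalty` (default `5 * sigma^2 * log(n)`, a BIC-style penalty
#' with `sigma` estimated robustly by [dlr_spread()]).  Adjacent segments
#' whose means differ by less than twice the standard error of the
#' difference are merged.  Deterministic.
#'
#' @param profile An `acgh_profile`.
#' @param min_seg_probes Minimum probes per segment.
#' @param penalty RSS-reduction acceptance threshold; `NULL` for the
#'   default.
#' @return data.frame of class `acgh_segments`: `start_idx`/`end_idx`
#'   (0-based half-open probe indices), `start_bp`/`end_bp`, `n_probes`,
#'   `mean_log2`, `fraction_estimate`.  Segments partition the profile.
#' @export
segment_profile <- function(profile, min_seg_probes = 10L, penalty = NULL) {
  x <- profile$log2_ratio
  n <- length(x)
  stopifnot(n >= 2L * min_seg_probes)
  sigma <- max(dlr_spread(profile), 1e-6)
  penalty <- penalty %||% (5 * sigma^2 * log(n))

  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_rss <- function(a, b) {  # probes a..b 1-based inclusive
    s <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    s2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    s2 - s^2 / (b - a + 1L)
  }
  boundaries <- integer(0)  # 0-based split points
  recurse <- function(a, b) {
    if (b - a + 1L < 2L * min_seg_probes) return(invisible())
    ks <- (a + min_seg_probes - 1L):(b - min_seg_probes)  # last idx of left
    base <- seg_rss(a, b)
    red <- vapply(ks, function(k) base - seg_rss(a, k) - seg_rss(k + 1L, b),
                  numeric(1))
    k <- ks[which.max(red)]
    if (max(red) > penalty) {
      boundaries <<- c(boundaries, k)
      recurse(a, k)
      recurse(k + 1L, b)
    }
    invisible()
  }
  recurse(1L, n)
  bnd <- sort(unique(boundaries))
  starts <- c(1L, bnd + 1L)
  ends <- c(bnd, n)

  # merge adjacent segments whose means are statistically indistinguishable
  repeat {
    if (length(starts) == 1L) break
    m <- mapply(function(a, b) (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1),
                starts, ends)
    nn <- ends - starts + 1L
    merged <- FALSE
    for (i in seq_len(length(starts) - 1L)) {
      se <- sigma * sqrt(1 / nn[i] + 1 / nn[i + 1L])
      if (abs(m[i] - m[i + 1L]) < 2 * se) {
        ends[i] <- ends[i + 1L]
        starts <- starts[-(i + 1L)]; ends <- ends[-(i + 1L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  # local boundary refinement: greedy splits can land a probe or two off
  # the RSS-optimal boundary once the neighbouring segments are known
  if (length(starts) > 1L) {
    for (pass in 1:5) {
      moved <- FALSE
      for (i in seq_len(length(starts) - 1L)) {
        a <- starts[i]; b <- ends[i + 1L]
        ks <- (a + min_seg_probes - 1L):(b - min_seg_probes)
        rss <- vapply(ks, function(k) seg_rss(a, k) + seg_rss(k + 1L, b),
                      numeric(1))
        k_best <- ks[which.min(rss)]
        if (k_best != ends[i]) {
          ends[i] <- k_best
          starts[i + 1L] <- k_best + 1L
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }

  m <- mapply(function(a, b) mean(x[a:b]), starts, ends)
  out <- data.frame(start_idx = starts - 1L, end_idx = ends,
                    start_bp = profile$position[starts],
                    end_bp = profile$position[ends],
                    n_probes = ends - starts + 1L,
                    mean_log2 = as.numeric(m),
                    fraction_estimate = estimate_fraction(as.numeric(m)))
  class(out) <- c("acgh_segments", "data.frame")
  out
}

#' Call a stepped (nested) mosaic terminal deletion
#'
#' Interprets segmented means as a nested mosaic: a maximal terminal run of
#' segments with strictly more-negative means toward the telomere (the
#' profile end).  Emits the breakpoints at the segment boundaries and the
#' per-step deleted-cell fractions, which must be non-decreasing toward the
#' telomere.  A profile whose post-baseline segments are not monotone is
#' rejected (`monotone = FALSE`, no breakpoints).
#'
#' @param segments An `acgh_segments` table (ordered by position).
#' @param tol Mean-difference tolerance for the monotonicity check.
#' @return `list(breakpoints_bp, breakpoint_idx, fractions, monotone,
#'   diagnostic)` of class `stepped_mosaic_call`; `breakpoint_idx` are the
#'   0-based probe indices at which each new (more deleted) segment starts.
#' @export
call_stepped_mosaic <- function(segments, tol = 0.02) {
  stopifnot(inherits(segments, "data.frame"), nrow(segments) >= 1L)
  m <- segments$mean_log2
  k <- nrow(segments)
  if (k == 1L) {
    out <- list(breakpoints_bp = numeric(0), breakpoint_idx = integer(0),
                fractions = numeric(0), monotone = TRUE,
                diagnostic = "flat profile")
    class(out) <- "stepped_mosaic_call"
    return(out)
  }
  steps <- diff(m)
  if (any(steps > tol)) {
    out <- list(breakpoints_bp = numeric(0), breakpoint_idx = integer(0),
                fractions = numeric(0), monotone = FALSE,
                diagnostic = sprintf(
                  "segment means not monotone toward the telomere (step %d rises by %.3f)",
                  which(steps > tol)[1L], max(steps)))
    class(out) <- "stepped_mosaic_call"
    return(out)
  }
  out <- list(breakpoints_bp = segments$start_bp[-1L],
              breakpoint_idx = segments$start_idx[-1L],
              fractions = segments$fraction_estimate[-1L],
              monotone = TRUE,
              diagnostic = sprintf("%d nested deletion steps", k - 1L))
  class(out) <- "stepped_mosaic_call"
  out
}

#' @export
print.stepped_mosaic_call <- function(x, ...) {
  if (!x$monotone) {
    cat("stepped mosaic call rejected:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("stepped mosaic: %d breakpoint(s)\n", length(x$breakpoint_idx)))
  if (length(x$breakpoint_idx)) {
    cat(sprintf("  BP%d at probe %d (%.0f bp), deleted fraction %.3f\n",
                seq_along(x$breakpoint_idx), x$breakpoint_idx,
                x$breakpoints_bp, x$fractions), sep = "")
  }
  invisible(x)
}

#' Read and write probe-level profiles as TSV
#'
#' Two tab-separated columns: `position`, `log2_ratio`.
#'
#' @param path File path.
#' @return For `read_profile_tsv`, an `acgh_profile`.
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("position", "log2_ratio") %in% names(df)),
            !is.unsorted(df$position, strictly = TRUE),
            all(is.finite(df$log2_ratio)))
  class(df) <- c("acgh_profile", "data.frame")
  df
}

#' @rdname read_profile_tsv
#' @param profile An `acgh_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile[, c("position", "log2_ratio")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
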