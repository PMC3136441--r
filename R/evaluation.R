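# Round-trip evaluation harnesses: simulate junctions with known truth,
# run the full analysis, and score label accuracy and evidence recovery.
# Used by the validation suite and the reproduction script.

#' Simulate-and-recall evaluation over all six mechanisms
#'
#' For each mechanism, simulates `n_per` junctions with drawn parameters
#' (seeds `seed_offset + 1 .. seed_offset + 6 * n_per`, assigned
#' mechanism-wise), optionally applies uniform substitution noise to the
#' reads, then calls and classifies every junction and scores it against
#' its truth record.
#'
#' A junction scores `exact` when the label and subtype are correct and
#' the recovered microhomology, untemplated insert, telomere copy number
#' and templated-insert interval (whichever apply) equal the truth
#' exactly, with the true breakpoint inside the reported breakpoint
#' interval.  `bp_within2` counts junctions whose true proximal breakpoint
#' lies within 2 bp of the reported interval.
#'
#' @param ref A [build_reference()] genome.
#' @param n_per Junctions per mechanism.
#' @param noise_rate Per-base read substitution rate (0 = noiseless).
#' @param capture_mut_rate Divergence of captured donor blocks.
#' @param seed_offset Added to every simulation seed.
#' @return `list(n, label_correct, exact, bp_within2, per_mechanism)`.
#' @export
evaluate_round_trip <- function(ref, n_per = 100L, noise_rate = 0,
                                capture_mut_rate = 0, seed_offset = 0L) {
  mechs <- c("telomere_healing", "telomere_capture", "ring_junction",
             "translocation", "nhej_interstitial", "fostes_mmbir")
  res <- expand.grid(mechanism = mechs, i = seq_len(n_per),
                     stringsAsFactors = FALSE)
  res$label_ok <- res$exact <- res$bp_ok <- FALSE
  for (r in seq_len(nrow(res))) {
    m <- match(res$mechanism[r], mechs)
    seed <- seed_offset + (m - 1L) * n_per + res$i[r]
    sim <- simulate_one(ref, res$mechanism[r], seed,
                        capture_mut_rate = capture_mut_rate)
    read <- sim$record$seq
    if (noise_rate > 0) {
      read <- mutate_sequence(read, noise_rate, derive_seed(seed, 7L))
    }
    cl <- call_junction(read, ref)
    lab <- classify_junction(cl)
    want <- expected_label(sim$truth)
    tr <- sim$truth
    lgood <- identical(lab$label, want$label) &&
      identical(lab$subtype, want$subtype)
    bp <- cl$breakpoint_interval
    bdist <- if (is.null(bp)) Inf else {
      max(0L, bp$start - tr$breakpoints[1], tr$breakpoints[1] - (bp$end - 1L))
    }
    ex <- lgood
    if (is.null(tr$template_insert)) {
      ex <- ex && identical(cl$microhomology_len, tr$fusion_microhomology)
    } else {
      ti <- tr$template_insert
      ex <- ex && !is.null(cl$template_insert) &&
        identical(as.integer(cl$template_insert$interval),
                  as.integer(ti$interval)) &&
        identical(cl$template_insert$orientation, ti$orientation) &&
        identical(cl$template_insert$mh_prox, as.integer(ti$mh_prox)) &&
        identical(cl$template_insert$mh_dist, as.integer(ti$mh_dist))
    }
    ex <- ex && identical(cl$untemplated_insert, tr$untemplated_insertion)
    if (tr$mechanism == "telomere_healing") {
      ex <- ex && identical(cl$distal$anchor$copies,
                            as.integer(tr$hexamer_copies))
    }
    ex <- ex && bdist == 0L
    res$label_ok[r] <- lgood
    res$exact[r] <- ex
    res$bp_ok[r] <- bdist <= 2L
  }
  per <- aggregate(cbind(label_ok, exact, bp_ok) ~ mechanism, data = res,
                   FUN = sum)
  list(n = nrow(res),
       label_correct = sum(res$label_ok),
       exact = sum(res$exact),
       bp_within2 = sum(res$bp_ok),
       per_mechanism = per)
}

#' Stepped-mosaic recovery evaluation
#'
#' Simulates a nested three-step mosaic terminal-deletion profile
#' (generating segment means `0, -0.3, -0.5, -0.8`, the canonical
#' three-cell-line pattern) for each seed, segments it and scores
#' recovery: segment count, largest mean error, largest boundary error
#' (probes), and monotonicity of the fraction estimates.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param noise_sd Probe noise standard deviation.
#' @param probes_per_seg Probes per generating segment.
#' @param spacing Probe spacing (bp).
#' @return data.frame with one row per seed: `n_segments`,
#'   `max_mean_err`, `max_bp_err_probes`, `monotone`, `step1_fraction`.
#' @export
evaluate_stepped_mosaic <- function(seeds = 1:20, noise_sd = 0.1,
                                    probes_per_seg = 250L, spacing = 400L) {
  gen_means <- c(0, -0.3, -0.5, -0.8)
  fr <- estimate_fraction(gen_means)
  seg_tbl <- data.frame(length_bp = rep(probes_per_seg * spacing, 4L),
                        fraction = fr)
  truth_bounds <- probes_per_seg * (1:3)
  out <- lapply(seeds, function(s) {
    prof <- simulate_profile(seg_tbl, spacing = spacing, noise_sd = noise_sd,
                             seed = s)
    segs <- segment_profile(prof)
    call <- call_stepped_mosaic(segs)
    if (nrow(segs) == 4L) {
      data.frame(seed = s, n_segments = 4L,
                 max_mean_err = max(abs(segs$mean_log2 - gen_means)),
                 max_bp_err_probes = max(abs(segs$start_idx[-1] -
                                               truth_bounds)),
                 monotone = call$monotone,
                 step1_fraction = segs$fraction_estimate[2L])
    } else {
      data.frame(seed = s, n_segments = nrow(segs), max_mean_err = NA_real_,
                 max_bp_err_probes = NA_real_, monotone = FALSE,
                 step1_fraction = NA_real_)
    }
  })
  do.call(rbind, out)
}
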