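# Synthetic reference and rearrangement simulator.
#
# The toy reference compresses the architecture of a distal chromosome arm
# into 200 kb: random-background chromatin, a handful of identical repeat
# decoys on the "p-arm" side, a near-identical paralog block shared with a
# second sequence (the RABL2A/RABL2B situation), a GC-rich hotspot, a
# 2 kb TAR (telomere-associated repeat) block and a terminal (GGTTAG)n
# array.  Junction signatures (hexamer copy numbers, microhomology and
# insert lengths) are kept at literal size because the analysis is local;
# only genomic distances are scaled down.

#' Simulation configuration
#'
#' Defaults describe the toy reference: a 200 kb main chromosome (`chrT`)
#' ending in a 2 kb TAR block plus a 50-unit (GGTTAG)n telomere array, and a
#' 60 kb second chromosome (`chrB`) carrying a near-identical paralog of a
#' `chrT` block and its own subtelomere (the capture donor).
#'
#' @param chr_len Length of the main chromosome `chrT` in bp.
#' @param chrB_len Length of the second chromosome `chrB` in bp.
#' @param tar_len Length of the TAR block immediately proximal to the
#'   `chrT` telomere array.
#' @param telomere_units Number of canonical GGTTAG units in each telomere
#'   array (must be >= 1).
#' @param paralog_len Length of the duplicated paralog block.
#' @param paralog_identity Sequence identity between the two paralog copies.
#' @param decoy_len,decoy_copies Length and copy number of the identical
#'   repeat decoy.
#' @param subtel_len Length of the `chrB` foreign-subtelomere block.
#' @param gc Target GC fraction of the random background.
#' @param max_del Longest deletion the simulators may draw; chromosomes
#'   shorter than ten times this are rejected.
#' @param flank_len Proximal flank length carried by every simulated read.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chr_len = 200000L, chrB_len = 60000L, tar_len = 2000L,
                       telomere_units = 50L, paralog_len = 2000L,
                       paralog_identity = 0.995, decoy_len = 400L,
                       decoy_copies = 3L, subtel_len = 450L, gc = 0.48,
                       max_del = 15000L, flank_len = 200L) {
  cfg <- list(chr_len = as.integer(chr_len), chrB_len = as.integer(chrB_len),
              tar_len = as.integer(tar_len),
              telomere_units = as.integer(telomere_units),
              paralog_len = as.integer(paralog_len),
              paralog_identity = paralog_identity,
              decoy_len = as.integer(decoy_len),
              decoy_copies = as.integer(decoy_copies),
              subtel_len = as.integer(subtel_len), gc = gc,
              max_del = as.integer(max_del), flank_len = as.integer(flank_len))
  class(cfg) <- "sim_config"
  cfg
}

#' Build the toy reference genome
#'
#' Deterministic for a given `(config, seed)`.  `chrT` ends in
#' `[TAR block][telomere array]`; `chrB` carries the paralog copy and a
#' 450 bp subtelomeric block followed by its own telomere array.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `reference_genome`: `sequences` (named list of
#'   uppercase DNA strings), `features` (data.frame with `seq_name`,
#'   `start`, `end` 0-based half-open, `kind`, `label`), `seed`, `config`.
#' @export
build_reference <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$telomere_units < 1L) {
    stop("telomere_units must be >= 1", call. = FALSE)
  }
  if (config$chr_len < 10L * config$max_del) {
    stop("chr_len must be at least 10x the longest simulated deletion",
         call. = FALSE)
  }
  telo_len <- 6L * config$telomere_units
  L <- config$chr_len
  LB <- config$chrB_len
  withr::with_seed(seed, {
    chrT <- random_dna(L, gc = config$gc)
    chrB <- random_dna(LB, gc = config$gc)

    feat <- function(seq_name, start, end, kind, label) {
      data.frame(seq_name = seq_name, start = as.integer(start),
                 end = as.integer(end), kind = kind, label = label,
                 stringsAsFactors = FALSE)
    }
    features <- list()

    # identical repeat decoys on the p-arm side of chrT
    decoy <- random_dna(config$decoy_len, gc = config$gc)
    decoy_at <- as.integer(L * c(0.025, 0.06, 0.10))[seq_len(config$decoy_copies)]
    for (i in seq_along(decoy_at)) {
      p <- decoy_at[i]
      substr(chrT, p + 1L, p + config$decoy_len) <- decoy
      features[[length(features) + 1L]] <-
        feat("chrT", p, p + config$decoy_len, "repeat_decoy",
             sprintf("decoy_copy%d", i))
    }

    # gene model (annotation only) and GC-rich hotspot
    g1 <- as.integer(L * 0.70)
    features[[length(features) + 1L]] <-
      feat("chrT", g1, g1 + 6000L, "gene_model", "shank3_like")
    h1 <- as.integer(L * 0.75)
    hot <- random_dna(200L, gc = 0.9)
    substr(chrT, h1 + 1L, h1 + 200L) <- hot
    features[[length(features) + 1L]] <-
      feat("chrT", h1, h1 + 200L, "gc_rich_hotspot", "intron8_gc_repeat")

    # paralog block: chrT copy is background; chrB carries a diverged copy
    p1 <- as.integer(L * 0.80)
    pb <- s0(chrT, p1, p1 + config$paralog_len)
    features[[length(features) + 1L]] <-
      feat("chrT", p1, p1 + config$paralog_len, "paralog_block", "rabl2b_like")
    pB <- as.integer(LB * 0.17)
    pb2 <- mutate_sequence(pb, 1 - config$paralog_identity, seed + 101L)
    substr(chrB, pB + 1L, pB + config$paralog_len) <- pb2
    features[[length(features) + 1L]] <-
      feat("chrB", pB, pB + config$paralog_len, "paralog_block", "rabl2a_like")

    # chrT subtelomere: TAR block then terminal telomere array
    tar_start <- L - telo_len - config$tar_len
    features[[length(features) + 1L]] <-
      feat("chrT", tar_start, L - telo_len, "tar_block", "chrT_tar")
    substr(chrT, L - telo_len + 1L, L) <-
      strrep("GGTTAG", config$telomere_units)
    features[[length(features) + 1L]] <-
      feat("chrT", L - telo_len, L, "telomere_array", "chrT_telomere")

    # chrB subtelomere (capture donor, Xp/Yp-like) and telomere array
    subB <- LB - telo_len - config$subtel_len
    features[[length(features) + 1L]] <-
      feat("chrB", subB, LB - telo_len, "tar_block", "xpyp_subtelomere")
    substr(chrB, LB - telo_len + 1L, LB) <-
      strrep("GGTTAG", config$telomere_units)
    features[[length(features) + 1L]] <-
      feat("chrB", LB - telo_len, LB, "telomere_array", "chrB_telomere")

    ref <- list(sequences = list(chrT = chrT, chrB = chrB),
                features = do.call(rbind, features),
                seed = as.integer(seed), config = config)
    class(ref) <- "reference_genome"
    ref
  })
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:",
      paste(sprintf("%s (%d bp)", names(x$sequences),
                    nchar(unlist(x$sequences))), collapse = ", "), "\n")
  cat(nrow(x$features), "feature annotations; seed", x$seed, "\n")
  invisible(x)
}

ref_seq <- function(ref, name) {
  s <- ref$sequences[[name]]
  if (is.null(s)) stop("unknown sequence: ", name, call. = FALSE)
  s
}

# Does [start, end) overlap any feature of the given kinds on seq_name?
overlaps_feature <- function(ref, seq_name, start, end,
                             kinds = c("repeat_decoy", "paralog_block",
                                       "tar_block", "telomere_array",
                                       "gc_rich_hotspot")) {
  f <- ref$features
  any(f$seq_name == seq_name & f$kind %in% kinds &
        f$start < end & f$end > start)
}

feature_interval <- function(ref, kind, seq_name, label = NULL) {
  f <- ref$features
  sel <- f$kind == kind & f$seq_name == seq_name
  if (!is.null(label)) sel <- sel & f$label == label
  f <- f[sel, , drop = FALSE]
  if (nrow(f) == 0L) stop("no such feature: ", kind, call. = FALSE)
  c(f$start[1L], f$end[1L])
}

# Spiral search around `target` for the first position satisfying `pred`.
search_position <- function(target, lo, hi, pred, max_radius = 40000L) {
  target <- as.integer(target)
  for (r in 0:max_radius) {
    for (b in if (r == 0L) target else c(target + r, target - r)) {
      if (b >= lo && b <= hi && isTRUE(pred(b))) return(b)
    }
  }
  stop("could not place a junction satisfying the requested constraints",
       call. = FALSE)
}

hex_suffix <- function(k) if (k == 0L) "" else substr("GGTTAG", 7L - k, 6L)

# Flank acceptability: inside bounds and outside multi-copy features, so the
# proximal anchor is uniquely mappable.
clear_flank <- function(ref, seq_name, b, flank_len, after = 0L) {
  b - flank_len >= 0L && b + after <= nchar(ref_seq(ref, seq_name)) &&
    !overlaps_feature(ref, seq_name, b - flank_len, b + after,
                      kinds = c("repeat_decoy", "paralog_block"))
}

new_truth <- function(id, mechanism, seq_name, breakpoints, del_size = NULL,
                      hexamer_copies = NULL, fusion_microhomology = 0L,
                      untemplated_insertion = "", template_insert = NULL,
                      source = NULL, source_interval = NULL, seed = NA_integer_,
                      ambiguous_distal = FALSE, noise_rate = 0) {
  tr <- list(id = id, mechanism = mechanism, seq_name = seq_name,
             breakpoints = as.integer(breakpoints),
             del_size = if (is.null(del_size)) NULL else as.integer(del_size),
             hexamer_copies = hexamer_copies,
             fusion_microhomology = as.integer(fusion_microhomology),
             untemplated_insertion = untemplated_insertion,
             template_insert = template_insert, source = source,
             source_interval = source_interval, seed = as.integer(seed),
             ambiguous_distal = ambiguous_distal, noise_rate = noise_rate)
  class(tr) <- "rearrangement_truth"
  tr
}

# Observed junction microhomology between ref@b1 (proximal, sequence sA) and
# ref@b2 (distal, sequence sB): right extension past b1 along the distal
# continuation plus left extension of the distal reference into the proximal
# flank.  This is the brute-force definition the analyzer must reproduce.
observed_mh <- function(ref, sA, b1, sB, b2, cap = 12L) {
  A <- ref_seq(ref, sA); B <- ref_seq(ref, sB)
  right <- lcp_len(s0(A, b1, b1 + cap), s0(B, b2, b2 + cap), cap = cap)
  left <- lcs_len(s0(A, b1 - cap, b1), s0(B, b2 - cap, b2), cap = cap)
  right + left
}

#' Simulate a telomere-healing junction read
#'
#' Emits a read `[proximal flank][untemplated insert][copies x GGTTAG]`
#' together with its truth record.  When `mh > 0` the breakpoint is placed
#' (searching outward from the position implied by `del_size`) so that the
#' reference suffix equals the in-phase GGTTAG suffix of length `mh`, and
#' exactly that length: the preceding reference base breaks the match.
#'
#' @param ref A [build_reference()] genome.
#' @param del_size Terminal deletion size in bp (drawn uniformly from
#'   3000-15000 when `NULL`).
#' @param copies Number of GGTTAG units appended (>= 1).
#' @param mh Fusion microhomology with the canonical hexamer, 0-5.  Value 6
#'   is rejected: a full absorbed unit makes breakpoint phase ambiguous.
#' @param insert Untemplated insertion placed between flank and array;
#'   requires `mh = 0`.
#' @param seed Integer seed.
#' @param flank_len Proximal flank length (>= 150).
#' @return `list(record = list(id, seq), truth = rearrangement_truth)`.
#' @export
simulate_terminal_healing <- function(ref, del_size = NULL, copies = 6L,
                                      mh = 0L, insert = "", seed = 1L,
                                      flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"), copies >= 1L, flank_len >= 150L)
  mh <- as.integer(mh)
  if (mh < 0L || mh > 5L) {
    stop("fusion microhomology must be in 0..5 (6 is phase-ambiguous)",
         call. = FALSE)
  }
  if (nchar(insert) > 0L) {
    check_dna(insert, "insert")
    if (mh != 0L) {
      stop("untemplated insert and engineered microhomology are mutually ",
           "exclusive", call. = FALSE)
    }
  }
  chrT <- ref_seq(ref, "chrT")
  L <- nchar(chrT)
  withr::with_seed(seed, {
    if (is.null(del_size)) del_size <- as.integer(runif(1, 3000, 15000))
    if (del_size >= L) stop("del_size beyond chromosome length", call. = FALSE)
    tar_start <- feature_interval(ref, "tar_block", "chrT")[1L]
    suf <- hex_suffix(mh)
    pre_char <- substr("GGTTAG", 6L - mh, 6L - mh)  # canonical char before suffix
    ok_b <- function(b) {
      if (!clear_flank(ref, "chrT", b, flank_len)) return(FALSE)
      if (b > tar_start - 10L) return(FALSE)
      if (mh > 0L && s0(chrT, b - mh, b) != suf) return(FALSE)
      # exactness: longer in-phase match must fail
      if (substr(chrT, b - mh, b - mh) == pre_char) return(FALSE)
      # guard: deleted-region continuation must not mimic the first unit,
      # so analysis-side re-attribution of leading units is unambiguous
      if (s0(chrT, b, b + 6L) == "GGTTAG") return(FALSE)
      if (nchar(insert) > 0L && substr(insert, 1L, 1L) == s0(chrT, b, b + 1L)) {
        return(FALSE)
      }
      TRUE
    }
    b <- search_position(L - del_size, flank_len, tar_start - 10L, ok_b)
    if (nchar(insert) > 0L) {
      # the 6-mer window ending at the array start must not pass for a
      # telomere unit, or the copy count would be inflated by absorption
      win <- paste0(s0(chrT, b - 6L, b), insert)
      win <- substr(win, nchar(win) - 5L, nchar(win))
      dist <- sum(strsplit(win, "")[[1]] != strsplit("GGTTAG", "")[[1]])
      if (dist <= 1L) {
        stop("insert suffix mimics a telomere unit; choose another insert",
             call. = FALSE)
      }
    }
    read <- paste0(s0(chrT, b - flank_len, b), insert,
                   strrep("GGTTAG", copies))
    id <- sprintf("healing_s%d", seed)
    truth <- new_truth(id, "telomere_healing", "chrT", b, del_size = L - b,
                       hexamer_copies = as.integer(copies),
                       fusion_microhomology = if (nchar(insert)) 0L else mh,
                       untemplated_insertion = insert, seed = seed)
    list(record = list(id = id, seq = read), truth = truth)
  })
}

#' Simulate a telomere-capture junction read
#'
#' The read suffix is a copy (optionally mutated at `mut_rate`) of a donor
#' block -- the distal 450 bp of the `chrT` TAR block or the `chrB`
#' foreign subtelomere -- followed by the donor's telomere array.
#'
#' @inheritParams simulate_terminal_healing
#' @param source `"tar_block"` or `"foreign_subtelomere"`.
#' @param mut_rate Substitution rate applied to the captured block
#'   (default 0.005; the appended telomere array is copied verbatim).
#' @return `list(record, truth)`; the truth records the donor interval and
#'   the junction microhomology actually present at the fusion.
#' @export
simulate_telomere_capture <- function(ref, del_size = NULL,
                                      source = c("tar_block",
                                                 "foreign_subtelomere"),
                                      seed = 1L, mut_rate = 0.005,
                                      flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"))
  source <- match.arg(source)
  chrT <- ref_seq(ref, "chrT")
  L <- nchar(chrT)
  cap_len <- ref$config$subtel_len
  withr::with_seed(seed, {
    if (is.null(del_size)) del_size <- as.integer(runif(1, 3000, 15000))
    if (del_size >= L) stop("del_size beyond chromosome length", call. = FALSE)
    tar_start <- feature_interval(ref, "tar_block", "chrT")[1L]
    b <- search_position(L - del_size, flank_len, tar_start - 10L,
                         function(b) clear_flank(ref, "chrT", b, flank_len))
    if (source == "tar_block") {
      donor_seq <- "chrT"
      tar <- feature_interval(ref, "tar_block", "chrT")
      src <- c(tar[2L] - cap_len, tar[2L])
    } else {
      donor_seq <- "chrB"
      src <- feature_interval(ref, "tar_block", "chrB")
      src <- c(src[2L] - cap_len, src[2L])
    }
    donor <- ref_seq(ref, donor_seq)
    block <- s0(donor, src[1L], src[2L])
    block <- mutate_sequence(block, mut_rate, seed + 211L)
    arr <- s0(donor, src[2L], nchar(donor))  # the donor telomere array
    read <- paste0(s0(chrT, b - flank_len, b), block, arr)
    # measured (not engineered) junction microhomology at the fusion
    mh_obs <- lcp_len(s0(chrT, b, b + 12L), block) +
      lcs_len(s0(chrT, b - 12L, b), s0(donor, src[1L] - 12L, src[1L]))
    id <- sprintf("capture_s%d", seed)
    truth <- new_truth(id, "telomere_capture", "chrT", b, del_size = L - b,
                       hexamer_copies = ref$config$telomere_units,
                       fusion_microhomology = mh_obs, source = source,
                       source_interval = as.integer(src), seed = seed)
    truth$source_seq <- donor_seq
    list(record = list(id = id, seq = read), truth = truth)
  })
}

#' Simulate an interstitial NHEJ deletion junction read
#'
#' The read spans `[proximal flank | insert | distal flank]`.  With
#' `mh > 0` the distal breakpoint is searched so that the bidirectional
#' junction overlap (prefix extension past the proximal breakpoint plus
#' suffix extension before the distal one) equals `mh` exactly; with an
#' insert, both insert boundaries are forced to mismatch the adjacent
#' reference so the untemplated bases are recovered verbatim.
#'
#' @inheritParams simulate_terminal_healing
#' @param mh Engineered junction microhomology (requires `insert = ""`).
#' @export
simulate_interstitial_nhej <- function(ref, del_size = NULL, mh = 0L,
                                       insert = "", seed = 1L,
                                       flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"))
  mh <- as.integer(mh)
  if (nchar(insert) > 0L) {
    check_dna(insert, "insert")
    if (mh != 0L) {
      stop("untemplated insert and engineered microhomology are mutually ",
           "exclusive", call. = FALSE)
    }
  }
  chrT <- ref_seq(ref, "chrT")
  L <- nchar(chrT)
  withr::with_seed(seed, {
    if (is.null(del_size)) del_size <- as.integer(runif(1, 2000, 8000))
    if (del_size >= L) stop("del_size beyond chromosome length", call. = FALSE)
    ins_first <- substr(insert, 1L, 1L)
    ins_last <- substr(insert, nchar(insert), nchar(insert))
    ok_b1 <- function(b) {
      clear_flank(ref, "chrT", b, flank_len) &&
        (nchar(insert) == 0L || s0(chrT, b, b + 1L) != ins_first)
    }
    b1 <- search_position(as.integer(runif(1, 0.15 * L, 0.55 * L)),
                          flank_len, L, ok_b1)
    ok_b2 <- function(b2) {
      if (!clear_flank(ref, "chrT", b2, 0L, after = flank_len)) return(FALSE)
      if (nchar(insert) > 0L) {
        s0(chrT, b2 - 1L, b2) != ins_last
      } else {
        observed_mh(ref, "chrT", b1, "chrT", b2) == mh
      }
    }
    b2 <- search_position(b1 + del_size, b1 + 500L, L - flank_len, ok_b2)
    read <- paste0(s0(chrT, b1 - flank_len, b1), insert,
                   s0(chrT, b2, b2 + flank_len))
    id <- sprintf("nhej_s%d", seed)
    truth <- new_truth(id, "nhej_interstitial", "chrT", c(b1, b2),
                       del_size = b2 - b1,
                       fusion_microhomology = if (nchar(insert)) 0L else mh,
                       untemplated_insertion = insert, seed = seed)
    list(record = list(id = id, seq = read), truth = truth)
  })
}

#' Simulate a FoSTeS/MMBIR junction with a templated insertion
#'
#' The read is `proximal flank | template | distal flank`, the template
#' being a 20-30 bp segment copied from the interior of the deleted
#' interval, by default in inverted (reverse-complement) orientation.  The
#' switch-point microhomologies `mh_prox`/`mh_dist` are engineered entirely
#' as anchor-side extensions so the maximal templated-insert match the
#' analyzer recovers coincides exactly with the recorded source interval.
#'
#' @inheritParams simulate_terminal_healing
#' @param template_len Template length in bp; 0 degenerates to plain NHEJ.
#' @param mh_prox,mh_dist Switch-point microhomologies at the proximal and
#'   distal template switches.
#' @param orientation `"reverse_complement"` (default) or `"forward"`.
#' @export
simulate_fostes <- function(ref, del_size = 8000L, template_len = 24L,
                            mh_prox = 4L, mh_dist = 2L,
                            orientation = c("reverse_complement", "forward"),
                            seed = 1L, flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"))
  orientation <- match.arg(orientation)
  template_len <- as.integer(template_len)
  if (template_len == 0L) {
    return(simulate_interstitial_nhej(ref, del_size = del_size, mh = 0L,
                                      seed = seed, flank_len = flank_len))
  }
  mh_prox <- as.integer(mh_prox); mh_dist <- as.integer(mh_dist)
  if (template_len - mh_prox - mh_dist < 15L) {
    stop("template_len minus switch microhomologies must leave >= 15 bp ",
         "of unclaimed template", call. = FALSE)
  }
  chrT <- ref_seq(ref, "chrT")
  L <- nchar(chrT)
  withr::with_seed(seed, {
    if (del_size >= L) stop("del_size beyond chromosome length", call. = FALSE)
    K <- 12L
    for (attempt in 1:25) {
      b1 <- search_position(as.integer(runif(1, 0.15 * L, 0.55 * L)),
                            flank_len, L,
                            function(b) clear_flank(ref, "chrT", b, flank_len))
      lo_t <- b1 + 300L
      hi_t <- b1 + del_size - 300L
      if (orientation == "reverse_complement") {
        # read-order template head = revcomp of ref ending at t2
        ok_t2 <- function(t2) {
          head <- revcomp(s0(chrT, t2 - K, t2))
          lcp_len(s0(chrT, b1, b1 + K), head, cap = K) == mh_prox &&
            s0(chrT, b1 - 1L, b1) != chartr("ACGT", "TGCA", s0(chrT, t2, t2 + 1L))
        }
        cand <- sample(seq.int(lo_t + template_len, hi_t))
        t2 <- NA_integer_
        for (x in cand) if (ok_t2(x)) { t2 <- x; break }
        if (is.na(t2)) next
        t1 <- t2 - template_len
        tail_read <- revcomp(s0(chrT, t1, t1 + K))
        ok_b2 <- function(b2) {
          if (!clear_flank(ref, "chrT", b2, 0L, after = flank_len)) return(FALSE)
          if (b2 <= t2 + 300L) return(FALSE)
          lcs_len(s0(chrT, b2 - K, b2), tail_read, cap = K) == mh_dist &&
            s0(chrT, b2, b2 + 1L) != chartr("ACGT", "TGCA", s0(chrT, t1 - 1L, t1))
        }
        b2 <- tryCatch(search_position(b1 + del_size, t2 + 301L,
                                       L - flank_len, ok_b2),
                       error = function(e) NA_integer_)
        if (is.na(b2)) next
        template <- revcomp(s0(chrT, t1, t2))
      } else {
        ok_t1 <- function(t1) {
          lcp_len(s0(chrT, b1, b1 + K), s0(chrT, t1, t1 + K), cap = K) == mh_prox &&
            s0(chrT, b1 - 1L, b1) != s0(chrT, t1 - 1L, t1)
        }
        cand <- sample(seq.int(lo_t, hi_t - template_len))
        t1 <- NA_integer_
        for (x in cand) if (ok_t1(x)) { t1 <- x; break }
        if (is.na(t1)) next
        t2 <- t1 + template_len
        ok_b2 <- function(b2) {
          if (!clear_flank(ref, "chrT", b2, 0L, after = flank_len)) return(FALSE)
          if (b2 <= t2 + 300L) return(FALSE)
          lcs_len(s0(chrT, b2 - K, b2), s0(chrT, t2 - K, t2), cap = K) == mh_dist &&
            s0(chrT, b2, b2 + 1L) != s0(chrT, t2, t2 + 1L)
        }
        b2 <- tryCatch(search_position(b1 + del_size, t2 + 301L,
                                       L - flank_len, ok_b2),
                       error = function(e) NA_integer_)
        if (is.na(b2)) next
        template <- s0(chrT, t1, t2)
      }
      read <- paste0(s0(chrT, b1 - flank_len, b1), template,
                     s0(chrT, b2, b2 + flank_len))
      id <- sprintf("fostes_s%d", seed)
      truth <- new_truth(id, "fostes_mmbir", "chrT", c(b1, b2),
                         del_size = b2 - b1,
                         template_insert = list(interval = c(t1, t2),
                                                orientation = orientation,
                                                mh_prox = mh_prox,
                                                mh_dist = mh_dist),
                         seed = seed)
      return(list(record = list(id = id, seq = read), truth = truth))
    }
    stop("could not engineer the requested FoSTeS junction; try other ",
         "microhomology values or a larger deletion", call. = FALSE)
  })
}

#' Simulate a ring-chromosome fusion junction
#'
#' Joins a q-arm breakpoint of `chrT` to a locus on the p-arm side of the
#' same chromosome (circularization); no telomere array is present in the
#' read.  With `distal_in_decoy = TRUE` the p-arm locus falls inside one of
#' the identical repeat-decoy copies, so the distal assignment is ambiguous.
#'
#' @inheritParams simulate_terminal_healing
#' @param q_del_size Size of the terminal q-arm deletion.
#' @param mh Engineered junction microhomology (ignored when
#'   `distal_in_decoy`; the observed value is recorded instead).
#' @param distal_in_decoy Place the p-arm breakpoint inside a repeat decoy.
#' @export
simulate_ring_junction <- function(ref, q_del_size = NULL, mh = 0L,
                                   distal_in_decoy = FALSE, seed = 1L,
                                   flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"))
  chrT <- ref_seq(ref, "chrT")
  L <- nchar(chrT)
  withr::with_seed(seed, {
    if (is.null(q_del_size)) q_del_size <- as.integer(runif(1, 3000, 15000))
    if (q_del_size >= L) stop("q_del_size beyond chromosome length",
                              call. = FALSE)
    tar_start <- feature_interval(ref, "tar_block", "chrT")[1L]
    b1 <- search_position(L - q_del_size, flank_len, tar_start - 10L,
                          function(b) clear_flank(ref, "chrT", b, flank_len))
    if (distal_in_decoy) {
      f <- ref$features
      d <- f[f$kind == "repeat_decoy" & f$seq_name == "chrT", ][1L, ]
      c_pos <- as.integer(d$start + 50L)
      mh_obs <- observed_mh(ref, "chrT", b1, "chrT", c_pos)
    } else {
      ok_c <- function(p) {
        clear_flank(ref, "chrT", p, 0L, after = flank_len) &&
          !overlaps_feature(ref, "chrT", p, p + flank_len) &&
          observed_mh(ref, "chrT", b1, "chrT", p) == mh
      }
      c_pos <- search_position(as.integer(runif(1, 1000L, 0.12 * L)),
                               500L, as.integer(0.14 * L), ok_c)
      mh_obs <- mh
    }
    read <- paste0(s0(chrT, b1 - flank_len, b1),
                   s0(chrT, c_pos, c_pos + flank_len))
    id <- sprintf("ring_s%d", seed)
    truth <- new_truth(id, "ring_junction", "chrT", c(b1, c_pos),
                       del_size = L - b1, fusion_microhomology = mh_obs,
                       ambiguous_distal = distal_in_decoy, seed = seed)
    list(record = list(id = id, seq = read), truth = truth)
  })
}

#' Simulate an unbalanced-translocation junction
#'
#' Joins a `chrT` q-arm breakpoint to a `chrB` locus with an engineered
#' junction microhomology.
#'
#' @inheritParams simulate_terminal_healing
#' @param mh Engineered junction microhomology.
#' @export
simulate_translocation_junction <- function(ref, mh = 4L, del_size = NULL,
                                            seed = 1L,
                                            flank_len = ref$config$flank_len) {
  stopifnot(inherits(ref, "reference_genome"))
  chrT <- ref_seq(ref, "chrT")
  chrB <- ref_seq(ref, "chrB")
  L <- nchar(chrT); LB <- nchar(chrB)
  withr::with_seed(seed, {
    if (is.null(del_size)) del_size <- as.integer(runif(1, 3000, 15000))
    tar_start <- feature_interval(ref, "tar_block", "chrT")[1L]
    b1 <- search_position(L - del_size, flank_len, tar_start - 10L,
                          function(b) clear_flank(ref, "chrT", b, flank_len))
    ok_c <- function(p) {
      clear_flank(ref, "chrB", p, 0L, after = flank_len) &&
        !overlaps_feature(ref, "chrB", p, p + flank_len) &&
        observed_mh(ref, "chrT", b1, "chrB", p) == mh
    }
    c_pos <- search_position(as.integer(runif(1, 0.25 * LB, 0.6 * LB)),
                             500L, LB - flank_len, ok_c)
    read <- paste0(s0(chrT, b1 - flank_len, b1),
                   s0(chrB, c_pos, c_pos + flank_len))
    id <- sprintf("transloc_s%d", seed)
    truth <- new_truth(id, "translocation", c("chrT", "chrB"), c(b1, c_pos),
                       del_size = L - b1, fusion_microhomology = mh,
                       seed = seed)
    list(record = list(id = id, seq = read), truth = truth)
  })
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + k) %% 2147483647)
}

#' Simulate a cohort of junction reads with truth records
#'
#' Draws `n` junctions from a mechanism mixture (default proportional to the
#' cohort class sizes 30:6:3:5 terminal:ring:translocation:interstitial,
#' with terminal split 27 healing : 3 capture and interstitial split
#' 4 NHEJ : 1 FoSTeS), with per-read parameters drawn from the ranges the
#' mechanisms are observed to span: 3-48 hexamer copies, 0-5 bp fusion
#' microhomologies, 0-20 bp untemplated insertions, 20-30 bp templates.
#'
#' @param ref A [build_reference()] genome.
#' @param n Number of reads.
#' @param mixture Named numeric weights over the six mechanisms
#'   (`telomere_healing`, `telomere_capture`, `ring_junction`,
#'   `translocation`, `nhej_interstitial`, `fostes_mmbir`).
#' @param seed Integer seed; record `i` uses a seed derived from
#'   `(seed, i)` so the run is reproducible read by read.
#' @param capture_mut_rate Substitution rate for captured donor blocks.
#' @param noise_rate Uniform read-level substitution rate applied to every
#'   emitted read (0 = noiseless).
#' @return `list(reads = named character vector, truth = named list)`.
#' @export
simulate_cohort <- function(ref, n = 44L, mixture = NULL, seed = 1L,
                            capture_mut_rate = 0.005, noise_rate = 0) {
  stopifnot(inherits(ref, "reference_genome"), n >= 1L)
  default_mix <- c(telomere_healing = 27, telomere_capture = 3,
                   ring_junction = 6, translocation = 3,
                   nhej_interstitial = 4, fostes_mmbir = 1)
  mixture <- mixture %||% default_mix
  stopifnot(all(names(mixture) %in% names(default_mix)), sum(mixture) > 0)
  counts <- withr::with_seed(seed, {
    drop(rmultinom(1L, n, mixture / sum(mixture)))
  })
  mechs <- rep(names(counts), counts)
  reads <- character(n)
  truths <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sim <- simulate_one(ref, mechs[i], si, capture_mut_rate)
    read <- sim$record$seq
    if (noise_rate > 0) {
      read <- mutate_sequence(read, noise_rate, derive_seed(si, 7L))
      sim$truth$noise_rate <- noise_rate
    }
    id <- sprintf("%s_%04d", mechs[i], i)
    sim$truth$id <- id
    ids[i] <- id
    reads[i] <- read
    truths[[i]] <- sim$truth
  }
  names(reads) <- ids
  names(truths) <- ids
  list(reads = reads, truth = truths)
}

#' Simulate a single junction of a given mechanism with drawn parameters
#'
#' Parameter draws (copy numbers, microhomologies, insert lengths, deletion
#' sizes) follow the same ranges as [simulate_cohort()]; used by it and by
#' the round-trip evaluations.
#'
#' @inheritParams simulate_cohort
#' @param mechanism One of the six mechanism names.
#' @export
simulate_one <- function(ref, mechanism, seed, capture_mut_rate = 0.005) {
  draw <- withr::with_seed(derive_seed(seed, 3L), {
    list(copies = sample(3:48, 1L), mh = sample(0:5, 1L),
         with_insert = runif(1) < 0.25,
         ins_len = sample(1:20, 1L),
         del = as.integer(runif(1, 3000, 15000)),
         del_i = as.integer(runif(1, 2000, 8000)),
         tlen = sample(20:30, 1L),
         mhp = sample(0:4, 1L), mhd = sample(0:4, 1L),
         src = sample(c("tar_block", "foreign_subtelomere"), 1L),
         ins = random_dna(sample(1:20, 1L)))
  })
  switch(mechanism,
    telomere_healing = {
      ins <- if (draw$with_insert) healing_safe_insert(draw$ins, seed) else ""
      simulate_terminal_healing(ref, del_size = draw$del, copies = draw$copies,
                                mh = if (nchar(ins)) 0L else draw$mh,
                                insert = ins, seed = seed)
    },
    telomere_capture = simulate_telomere_capture(
      ref, del_size = draw$del, source = draw$src, seed = seed,
      mut_rate = capture_mut_rate),
    ring_junction = simulate_ring_junction(ref, q_del_size = draw$del,
                                           mh = draw$mh, seed = seed),
    translocation = simulate_translocation_junction(ref, mh = draw$mh,
                                                    del_size = draw$del,
                                                    seed = seed),
    nhej_interstitial = simulate_interstitial_nhej(
      ref, del_size = draw$del_i,
      mh = if (draw$with_insert) 0L else draw$mh,
      insert = if (draw$with_insert) draw$ins else "", seed = seed),
    fostes_mmbir = {
      mhp <- draw$mhp; mhd <- draw$mhd
      while (draw$tlen - mhp - mhd < 15L) { mhp <- max(0L, mhp - 1L); mhd <- max(0L, mhd - 1L) }
      simulate_fostes(ref, del_size = 8000L, template_len = draw$tlen,
                      mh_prox = mhp, mh_dist = mhd, seed = seed)
    },
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  )
}

# Redraw an untemplated insert until its telomere-adjacent window cannot be
# mistaken for a hexamer unit.
healing_safe_insert <- function(ins, seed) {
  for (k in 0:50) {
    win <- if (nchar(ins) >= 6L) substr(ins, nchar(ins) - 5L, nchar(ins)) else NULL
    ok <- TRUE
    if (!is.null(win)) {
      dist <- sum(strsplit(win, "")[[1]] != strsplit("GGTTAG", "")[[1]])
      ok <- dist >= 2L
    } else {
      # short inserts: forbid suffixes of GGTTAG as whole insert
      ok <- ins != hex_suffix(nchar(ins))
    }
    if (ok) return(ins)
    ins <- withr::with_seed(derive_seed(seed, 900L + k),
                            random_dna(nchar(ins)))
  }
  ins
}

# ---- file I/O -------------------------------------------------------------

#' Write reference sequences as FASTA and features as BED
#'
#' @param ref A `reference_genome`.
#' @param fasta,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(ref, fasta = NULL, bed = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(unlist(ref$sequences))
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(bed)) {
    f <- ref$features
    bed_df <- data.frame(f$seq_name, f$start, f$end,
                         paste0(f$kind, ":", f$label))
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a reference genome from FASTA + BED
#'
#' Inverse of [write_reference()]; the BED name column is `kind:label`.
#'
#' @param fasta Path to the FASTA file.
#' @param bed Path to the features BED file.
#' @return A `reference_genome` (with `seed = NA`).
#' @export
read_reference <- function(fasta, bed) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.list(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  f <- read.delim(bed, header = FALSE,
                  col.names = c("seq_name", "start", "end", "name"))
  kind <- sub(":.*$", "", f$name)
  label <- sub("^[^:]*:", "", f$name)
  ref <- list(sequences = seqs,
              features = data.frame(seq_name = f$seq_name, start = f$start,
                                    end = f$end, kind = kind, label = label,
                                    stringsAsFactors = FALSE),
              seed = NA_integer_, config = sim_config())
  class(ref) <- "reference_genome"
  ref
}

#' Write simulated reads and truth records
#'
#' Reads go to `<prefix>.reads.fa`; truth records to `<prefix>.truth.jsonl`
#' (one JSON object per line, keyed by read id).
#'
#' @param sim Result of [simulate_cohort()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, prefix) {
  fa <- paste0(prefix, ".reads.fa")
  jl <- paste0(prefix, ".truth.jsonl")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reads), fa)
  con <- file(jl, "w")
  on.exit(close(con))
  for (tr in sim$truth) {
    writeLines(jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, null = "null"),
               con)
  }
  invisible(c(reads = fa, truth = jl))
}
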