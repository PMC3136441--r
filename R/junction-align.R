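# Junction-read decomposition against the reference: proximal anchor,
# distal assignment, junction microhomology, untemplated insertion and
# templated (FoSTeS/MMBIR-style) inserts.
#
# Alignment is deliberately simple -- exact k-mer seeding plus ungapped
# maximal-scoring extension -- because simulated junction fragments carry
# long, high-identity anchors; microhomology is then just the overlap of
# the two maximal anchors on the read, which provably equals the sum of
# the bidirectional breakpoint extensions.

#' Analysis configuration for junction calling
#'
#' @param seed_len Exact-match seed length.
#' @param min_anchor Minimum acceptable anchor length in bp.
#' @param min_identity Minimum anchor identity.
#' @param gap_max Maximum untemplated gap (bp) tolerated between the
#'   proximal anchor and a telomere array for the array to be called the
#'   distal partner (also the classifier's insert ceiling).
#' @param min_template Minimum templated-insert length searched for.
#' @param mh_max Maximum junction microhomology compatible with NHEJ.
#' @return List of class `junction_config`.
#' @export
junction_config <- function(seed_len = 20L, min_anchor = 40L,
                            min_identity = 0.95, gap_max = 20L,
                            min_template = 15L, mh_max = 10L) {
  cfg <- list(seed_len = as.integer(seed_len),
              min_anchor = as.integer(min_anchor),
              min_identity = min_identity, gap_max = as.integer(gap_max),
              min_template = as.integer(min_template),
              mh_max = as.integer(mh_max))
  class(cfg) <- "junction_config"
  cfg
}

ref_dna <- function(ref) {
  Biostrings::DNAStringSet(unlist(ref$sequences))
}

# Maximal-scoring ungapped extension of a seed placement.
# read position x (0-based) maps to reference position diag + x.
# Returns NULL or an anchor: q_start/q_end (read, 0-based half-open),
# ref_start/ref_end, n_matches, identity.
extend_seed <- function(read_ch, ref_ch, diag, seed_from, seed_to,
                        match = 1, mismatch = -3) {
  n <- length(read_ch)
  reflen <- length(ref_ch)
  lo <- max(0L, -diag)                 # first read pos with a ref partner
  hi <- min(n, reflen - diag)          # one past last such read pos
  if (seed_from < lo || seed_to > hi) return(NULL)
  # right extension from seed_to
  best_e <- seed_to; sc <- 0; best_sc <- 0
  x <- seed_to
  while (x < hi) {
    sc <- sc + if (read_ch[x + 1L] == ref_ch[diag + x + 1L]) match else mismatch
    x <- x + 1L
    if (sc > best_sc) { best_sc <- sc; best_e <- x }
    if (sc < best_sc - 12) break       # X-drop
  }
  # left extension from seed_from
  best_s <- seed_from; sc <- 0; best_sc <- 0
  x <- seed_from
  while (x > lo) {
    sc <- sc + if (read_ch[x] == ref_ch[diag + x]) match else mismatch
    x <- x - 1L
    if (sc > best_sc) { best_sc <- sc; best_s <- x }
    if (sc < best_sc - 12) break
  }
  qs <- best_s; qe <- best_e
  nm <- sum(read_ch[(qs + 1L):qe] == ref_ch[(diag + qs + 1L):(diag + qe)])
  list(q_start = qs, q_end = qe, ref_start = diag + qs, ref_end = diag + qe,
       n_matches = as.integer(nm), identity = nm / (qe - qs), diag = diag)
}

# Seed-and-extend anchoring of a read region against the whole reference.
# `seed_window` = c(from, to) 0-based half-open read interval the seeds are
# drawn from; extension is unrestricted.  Returns NULL or an anchor with
# seq_name, unique and ambiguity_count filled in.
find_anchor <- function(read, ref, seed_window, config = junction_config(),
                        dna = NULL, read_ch = NULL) {
  dna <- dna %||% ref_dna(ref)
  read_ch <- read_ch %||% strsplit(read, "", fixed = TRUE)[[1]]
  sl <- config$seed_len
  w0 <- seed_window[1L]; w1 <- seed_window[2L]
  offs <- unique(pmin(seq(w0, max(w0, w1 - sl), by = 7L), w1 - sl))
  offs <- offs[offs >= 0L]
  cands <- list()
  for (off in offs) {
    seed <- substr(read, off + 1L, off + sl)
    if (nchar(seed) < sl || grepl("[^ACGT]", seed)) next
    for (sn in names(ref$sequences)) {
      m <- Biostrings::matchPattern(seed, dna[[sn]])
      starts <- Biostrings::start(m) - 1L
      for (st in starts) {
        key <- paste0(sn, "@", st - off)
        if (is.null(cands[[key]])) cands[[key]] <- list(seq_name = sn,
                                                        diag = st - off,
                                                        off = off)
      }
    }
    if (length(cands) > 0L && off >= w0 + 14L) break  # enough seeds tried
  }
  if (length(cands) == 0L) return(NULL)
  anchors <- list()
  for (cd in cands) {
    ref_ch <- attr(dna, "chars")[[cd$seq_name]]
    a <- extend_seed(read_ch, ref_ch, cd$diag, cd$off, cd$off + sl)
    if (is.null(a)) next
    if (a$q_end - a$q_start < config$min_anchor) next
    if (a$identity < config$min_identity) next
    a$seq_name <- cd$seq_name
    anchors[[length(anchors) + 1L]] <- a
  }
  if (length(anchors) == 0L) return(NULL)
  nm <- vapply(anchors, `[[`, integer(1), "n_matches")
  o <- order(-nm)
  best <- anchors[[o[1L]]]
  near <- sum(nm >= nm[o[1L]] - 2L)
  best$unique <- near == 1L
  best$ambiguity_count <- as.integer(near)
  best$strand <- "+"
  class(best) <- "junction_anchor"
  best
}

# Character-vector cache for the reference, attached to the DNAStringSet.
prepare_dna <- function(ref) {
  dna <- ref_dna(ref)
  attr(dna, "chars") <- lapply(ref$sequences,
                               function(s) strsplit(s, "", fixed = TRUE)[[1]])
  dna
}

#' Anchor the proximal (prefix) side of a junction read
#'
#' Exact 20-mer seeds drawn from the read prefix, ungapped maximal-scoring
#' extension, >= 95% identity.  `unique` is `FALSE` when a second placement
#' ties the best within 2 matches (near-identical paralogs, repeat decoys).
#'
#' @param read Junction read (uppercase DNA, >= 60 bp).
#' @param ref A `reference_genome`.
#' @param config A [junction_config()].
#' @return A `junction_anchor` (fields `seq_name`, `ref_start`/`ref_end`,
#'   `q_start`/`q_end` 0-based half-open, `identity`, `unique`,
#'   `ambiguity_count`).
#' @export
anchor_proximal <- function(read, ref, config = junction_config()) {
  if (nchar(read) < 60L) stop("read must be at least 60 bp", call. = FALSE)
  dna <- prepare_dna(ref)
  a <- find_anchor(read, ref, c(0L, min(70L, nchar(read))), config, dna = dna)
  if (is.null(a) || a$q_start > 10L) {
    # prefix must be anchored; a placement starting deep in the read is not
    a <- if (!is.null(a) && a$q_start <= 10L) a else NULL
  }
  if (is.null(a)) stop("unanchored read", call. = FALSE)
  a
}

# Contiguous extension along a diagonal, with substitution tolerance.  The
# extension stops at a mismatch unless the mismatch looks like an isolated
# sequencing substitution rather than a junction: it is tolerated when
# either (a) the strict match run following it is >= `min_run` bases
# (random sequence past a junction sustains this with probability 4^-8), or
# (b) the following `look` bases contain at most `max_miss` further
# mismatches (tolerates nearby noise clusters; unattainable at ~25%
# post-junction identity).  Returns the first read position NOT attributed
# (dir = +1) or the first attributed position scanning leftward (dir = -1).
ext_contig <- function(read_ch, ref_ch, diag, from, dir = 1L, look = 20L,
                       max_miss = 2L, min_run = 8L) {
  n <- length(read_ch); rl <- length(ref_ch)
  x <- from
  repeat {
    probe <- if (dir > 0L) x else x - 1L
    rx <- diag + probe
    if (probe < 0L || probe >= n || rx < 0L || rx >= rl) break
    if (read_ch[probe + 1L] != ref_ch[rx + 1L]) {
      ahead <- probe + dir * seq_len(look)
      ra <- diag + ahead
      inb <- ahead >= 0L & ahead < n & ra >= 0L & ra < rl
      mm <- read_ch[ahead[inb] + 1L] != ref_ch[ra[inb] + 1L]
      run <- if (any(mm)) which(mm)[1L] - 1L else sum(inb)
      ok <- run >= min_run ||
        (sum(inb) == look && sum(mm) <= max_miss)
      if (!ok) break
    }
    x <- x + dir
  }
  x
}

#' Junction microhomology between two anchors
#'
#' The junction microhomology is the overlap, on the read, of the two
#' maximal contiguous anchor attributions: the proximal reference is
#' extended rightward from the read start along its diagonal and the distal
#' reference leftward from the read end; the overlap of the two extensions
#' equals the exhaustive bidirectional breakpoint extension (prefix match
#' past the proximal breakpoint plus suffix match before the distal one).
#' Every base inside the overlap matches both references, so the breakpoint
#' is ambiguous within an interval of width `len + 1`.  Zero when the
#' anchors abut or an untemplated gap separates them.  Isolated
#' substitutions (read noise) do not stop the extension; a junction does.
#'
#' @param proximal,distal `junction_anchor`s on the same read.
#' @param ref The `reference_genome` both anchors refer to.
#' @param read The read both anchors refer to.
#' @return `list(len, seq, p_eff, d_eff)`: `p_eff` is the first read
#'   position past the proximal attribution, `d_eff` the first position of
#'   the distal attribution; `d_eff > p_eff` indicates an untemplated gap.
#' @export
junction_microhomology <- function(proximal, distal, ref, read) {
  read_ch <- strsplit(read, "", fixed = TRUE)[[1]]
  chP <- strsplit(ref_seq(ref, proximal$seq_name), "", fixed = TRUE)[[1]]
  chD <- strsplit(ref_seq(ref, distal$seq_name), "", fixed = TRUE)[[1]]
  p_eff <- ext_contig(read_ch, chP, proximal$diag, proximal$q_start, 1L)
  d_eff <- ext_contig(read_ch, chD, distal$diag, distal$q_end, -1L)
  if (p_eff - d_eff > 50L) stop("anchor conflict", call. = FALSE)
  len <- max(0L, p_eff - d_eff)
  list(len = as.integer(len),
       seq = if (len > 0L) s0(read, d_eff, p_eff) else "",
       p_eff = p_eff, d_eff = d_eff)
}

#' Untemplated insertion between two anchors
#'
#' The read bases strictly between the maximal proximal and distal anchors;
#' empty when the anchors abut or overlap (microhomology and untemplated
#' insertion are mutually exclusive by definition).
#'
#' @inheritParams junction_microhomology
#' @return Character scalar (possibly "").
#' @export
detect_untemplated_insert <- function(read, proximal, distal) {
  p <- proximal$q_end; d <- distal$q_start
  if (d > p) s0(read, p, d) else ""
}

#' Locate an insert (or gap) as a templated copy of the deleted interval
#'
#' Finds the longest sub-segment of `insert_or_gap` (>= `min_len`) present
#' in `search_interval_seq` either forward or as a reverse complement.
#'
#' @param insert_or_gap The inter-anchor read bases.
#' @param search_interval_seq Sequence of the deleted interval to search.
#' @param min_len Minimum reportable template length.
#' @return `NULL` or `list(q_offset, len, src_start, orientation)` where
#'   `q_offset` is the 0-based offset of the matched sub-segment within
#'   `insert_or_gap` and `src_start` its 0-based offset within
#'   `search_interval_seq`.
#' @export
find_inverted_template <- function(insert_or_gap, search_interval_seq,
                                   min_len = 15L) {
  L <- nchar(insert_or_gap)
  if (L < min_len || nchar(search_interval_seq) < min_len) return(NULL)
  for (len in seq(L, min_len)) {
    for (st in 0:(L - len)) {
      sub <- substr(insert_or_gap, st + 1L, st + len)
      m <- regexpr(revcomp(sub), search_interval_seq, fixed = TRUE)[1L]
      if (m > 0L) {
        return(list(q_offset = st, len = as.integer(len),
                    src_start = m - 1L, orientation = "reverse_complement"))
      }
      m <- regexpr(sub, search_interval_seq, fixed = TRUE)[1L]
      if (m > 0L) {
        return(list(q_offset = st, len = as.integer(len),
                    src_start = m - 1L, orientation = "forward"))
      }
    }
  }
  NULL
}

# Extend a located template match maximally on the read against the
# reference source, in the stated orientation.  Coordinates:
#   u..v   read interval of the current match (0-based half-open)
#   t1..t2 reference interval of the source
compl1 <- function(x) chartr("ACGT", "TGCA", x)

extend_template <- function(read, refseq, u, v, t1, t2, orientation,
                            cap = 30L) {
  n <- nchar(read); rl <- nchar(refseq)
  if (orientation == "reverse_complement") {
    k <- 0L
    while (k < cap && u - k - 1L >= 0L && t2 + k < rl &&
           s0(read, u - k - 1L, u - k) == compl1(s0(refseq, t2 + k, t2 + k + 1L))) {
      k <- k + 1L
    }
    u <- u - k; t2 <- t2 + k
    k <- 0L
    while (k < cap && v + k < n && t1 - k - 1L >= 0L &&
           s0(read, v + k, v + k + 1L) == compl1(s0(refseq, t1 - k - 1L, t1 - k))) {
      k <- k + 1L
    }
    v <- v + k; t1 <- t1 - k
  } else {
    k <- 0L
    while (k < cap && u - k - 1L >= 0L && t1 - k - 1L >= 0L &&
           s0(read, u - k - 1L, u - k) == s0(refseq, t1 - k - 1L, t1 - k)) {
      k <- k + 1L
    }
    u <- u - k; t1 <- t1 - k
    k <- 0L
    while (k < cap && v + k < n && t2 + k < rl &&
           s0(read, v + k, v + k + 1L) == s0(refseq, t2 + k, t2 + k + 1L)) {
      k <- k + 1L
    }
    v <- v + k; t2 <- t2 + k
  }
  list(u = u, v = v, t1 = t1, t2 = t2)
}

# Re-attribute leading array units to the reference: a unit formed by
# reference flank bases (fusion microhomology 4-5 plus chance bases) can
# pass the Hamming<=1 run test; if its read bases match the reference
# diagonal they belong to the proximal side, not the array.
trim_array_to_ref <- function(arr, read, refseq, diag) {
  while (arr$copies > 1L) {
    u0 <- arr$start
    rs <- diag + u0
    if (rs < 0L || rs + 6L > nchar(refseq)) break
    if (s0(read, u0, u0 + 6L) != s0(refseq, rs, rs + 6L)) break
    arr$start <- arr$start + 6L
    arr$copies <- arr$copies - 1L
    keep <- arr$variant_units$offset >= arr$start
    dropped_var <- nrow(arr$variant_units) - sum(keep)
    arr$variant_units <- arr$variant_units[keep, , drop = FALSE]
    arr$canonical_copies <- arr$copies - nrow(arr$variant_units)
    arr$phase <- arr$start %% 6L
  }
  arr$canonical <- arr$canonical_copies / arr$copies >= 0.5
  arr
}

#' Assign the distal side of a junction read
#'
#' Tries, in order: an adjacent telomere array (within `gap_max` of the
#' proximal anchor), a TAR/foreign-subtelomere block, then any genomic
#' locus.  Returns a `distal_assignment` with `kind` in
#' `telomere_array`, `tar_block`, `foreign_subtelomere`, `genomic_locus`,
#' `unassigned`.
#'
#' @param read Junction read.
#' @param proximal The proximal `junction_anchor`.
#' @param ref Reference genome.
#' @param config A [junction_config()].
#' @return `list(kind, anchor (junction_anchor or telomere_array_hit),
#'   ambiguity_count, gap_to_array)`.
#' @export
assign_distal <- function(read, proximal, ref, config = junction_config()) {
  call <- decompose_junction(read, ref, config = config, proximal = proximal)
  call$distal
}

overlap_feature_kind <- function(ref, seq_name, start, end, kind) {
  f <- ref$features
  any(f$seq_name == seq_name & f$kind == kind & f$start < end & f$end > start)
}

# Full decomposition; the exported call_junction() wraps this with error
# capture.  `proximal` may be passed in to avoid re-anchoring.
decompose_junction <- function(read, ref, read_id = "read",
                               config = junction_config(), proximal = NULL,
                               dna = NULL) {
  check_dna(read, "read")
  dna <- dna %||% prepare_dna(ref)
  read_ch <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- nchar(read)
  if (n < 60L) stop("read must be at least 60 bp", call. = FALSE)
  prox <- proximal %||% {
    a <- find_anchor(read, ref, c(0L, min(70L, n)), config, dna = dna,
                     read_ch = read_ch)
    if (is.null(a) || a$q_start > 10L) stop("unanchored read", call. = FALSE)
    a
  }
  refseq <- ref_seq(ref, prox$seq_name)
  diag <- prox$ref_start - prox$q_start

  out <- list(read_id = read_id, proximal = prox, distal = NULL,
              microhomology_len = 0L, microhomology_seq = "",
              untemplated_insert = "", template_insert = NULL,
              breakpoint_interval = NULL, telomere_array = NULL,
              error = NULL)
  class(out) <- "junction_call"

  ref_ch <- attr(dna, "chars")[[prox$seq_name]]
  arr <- find_telomere_array(read)
  if (!is.null(arr) && arr$start >= 30L) {
    arr <- trim_array_to_ref(arr, read, refseq, diag)
    out$telomere_array <- arr
    # proximal attribution boundary by contiguous extension from read start
    p_eff <- ext_contig(read_ch, ref_ch, diag, prox$q_start)
    gap <- arr$start - p_eff
    if (gap <= config$gap_max) {
      b_hat <- diag + arr$start
      insert <- if (gap > 0L) s0(read, p_eff, arr$start) else ""
      mh <- 0L
      if (gap <= 0L && b_hat >= 6L) {
        mh <- telomere_fusion_microhomology(s0(refseq, b_hat - 12L, b_hat), arr)
      }
      out$distal <- list(kind = "telomere_array", anchor = arr,
                         ambiguity_count = 1L, gap_to_array = max(0L, gap))
      out$microhomology_len <- mh
      out$microhomology_seq <- if (mh > 0L) s0(refseq, b_hat - mh, b_hat) else ""
      out$untemplated_insert <- insert
      out$breakpoint_interval <- if (gap > 0L) {
        list(seq_name = prox$seq_name, start = diag + p_eff,
             end = diag + p_eff + 1L)
      } else {
        list(seq_name = prox$seq_name, start = b_hat - mh, end = b_hat + 1L)
      }
      return(out)
    }
    # array too far from the anchor: anchor the intervening segment
    seg_end <- arr$start
  } else {
    seg_end <- n
  }

  sw_from <- max(0L, min(prox$q_end, seg_end - config$seed_len))
  dist <- find_anchor(read, ref, c(sw_from, min(seg_end, sw_from + 70L)),
                      config, dna = dna, read_ch = read_ch)
  if (is.null(dist) && seg_end == n) {
    # fall back to seeding from the read end
    dist <- find_anchor(read, ref, c(max(0L, n - 70L), n), config,
                        dna = dna, read_ch = read_ch)
  }
  if (is.null(dist) ||
      (dist$seq_name == prox$seq_name && dist$diag == prox$diag)) {
    out$distal <- list(kind = "unassigned", anchor = NULL,
                       ambiguity_count = 0L)
    out$untemplated_insert <- s0(read, prox$q_end, seg_end)
    out$breakpoint_interval <- list(seq_name = prox$seq_name,
                                    start = prox$ref_end,
                                    end = prox$ref_end + 1L)
    return(out)
  }

  same_seq <- dist$seq_name == prox$seq_name
  tar_hit <- overlap_feature_kind(ref, dist$seq_name, dist$ref_start,
                                  dist$ref_end, "tar_block") ||
    overlap_feature_kind(ref, dist$seq_name, dist$ref_start, dist$ref_end,
                         "telomere_array")
  kind <- if (tar_hit && same_seq) "tar_block"
          else if (tar_hit) "foreign_subtelomere"
          else "genomic_locus"
  out$distal <- list(kind = kind, anchor = dist,
                     ambiguity_count = dist$ambiguity_count)

  res <- junction_microhomology(prox, dist, ref, read)
  p_eff <- res$p_eff; d_eff <- res$d_eff
  if (d_eff <= p_eff) {
    out$microhomology_len <- res$len
    out$microhomology_seq <- res$seq
    out$breakpoint_interval <- list(seq_name = prox$seq_name,
                                    start = diag + d_eff,
                                    end = diag + p_eff + 1L)
    return(out)
  }

  # untemplated gap between the two contiguous attributions
  gap_str <- s0(read, p_eff, d_eff)
  out$untemplated_insert <- gap_str
  out$microhomology_len <- 0L
  out$breakpoint_interval <- list(seq_name = prox$seq_name,
                                  start = diag + p_eff,
                                  end = diag + p_eff + 1L)

  if (nchar(gap_str) >= config$min_template && same_seq &&
      dist$ref_start > prox$ref_end) {
    del_from <- max(0L, diag + p_eff - 40L)
    del_to <- min(nchar(refseq), dist$diag + d_eff + 40L)
    hit <- find_inverted_template(gap_str, s0(refseq, del_from, del_to),
                                  min_len = config$min_template)
    if (!is.null(hit)) {
      u <- p_eff + hit$q_offset
      v <- u + hit$len
      t1 <- del_from + hit$src_start
      t2 <- t1 + hit$len
      ext <- extend_template(read, refseq, u, v, t1, t2, hit$orientation)
      out$template_insert <- list(
        seq_name = prox$seq_name,
        interval = c(ext$t1, ext$t2),
        orientation = hit$orientation,
        mh_prox = max(0L, p_eff - ext$u),
        mh_dist = max(0L, ext$v - d_eff))
      covered_from <- max(p_eff, ext$u); covered_to <- min(d_eff, ext$v)
      out$untemplated_insert <- paste0(s0(read, p_eff, covered_from),
                                       s0(read, covered_to, d_eff))
      # the proximal switch is ambiguous within its microhomology
      out$breakpoint_interval <- list(
        seq_name = prox$seq_name,
        start = diag + p_eff - out$template_insert$mh_prox,
        end = diag + p_eff + 1L)
    }
  }
  out
}

#' Decompose a junction read into a full junction call
#'
#' Deterministic composition of [anchor_proximal()], telomere-array
#' detection, distal assignment, microhomology/insert measurement and
#' templated-insert search.  Anchoring failures produce a structured error
#' record (field `error`) rather than an exception.
#'
#' @param read Junction read (uppercase DNA).
#' @param ref A `reference_genome`.
#' @param read_id Identifier carried into the call.
#' @param config A [junction_config()].
#' @return A `junction_call`.
#' @export
call_junction <- function(read, ref, read_id = "read",
                          config = junction_config()) {
  tryCatch(decompose_junction(read, ref, read_id = read_id, config = config),
           error = function(e) {
             out <- list(read_id = read_id, proximal = NULL,
                         distal = list(kind = "unassigned", anchor = NULL,
                                       ambiguity_count = 0L),
                         microhomology_len = NA_integer_,
                         microhomology_seq = "", untemplated_insert = "",
                         template_insert = NULL, breakpoint_interval = NULL,
                         telomere_array = NULL, error = conditionMessage(e))
             class(out) <- "junction_call"
             out
           })
}

#' Decompose many reads, sharing the reference index
#'
#' @param reads Named character vector of reads.
#' @param ref A `reference_genome`.
#' @param config A [junction_config()].
#' @return Named list of `junction_call`s.
#' @export
call_junctions <- function(reads, ref, config = junction_config()) {
  dna <- prepare_dna(ref)
  out <- vector("list", length(reads))
  ids <- names(reads) %||% sprintf("read%04d", seq_along(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- tryCatch(
      decompose_junction(reads[[i]], ref, read_id = ids[i], config = config,
                         dna = dna),
      error = function(e) {
        x <- list(read_id = ids[i], proximal = NULL,
                  distal = list(kind = "unassigned", anchor = NULL,
                                ambiguity_count = 0L),
                  microhomology_len = NA_integer_, microhomology_seq = "",
                  untemplated_insert = "", template_insert = NULL,
                  breakpoint_interval = NULL, telomere_array = NULL,
                  error = conditionMessage(e))
        class(x) <- "junction_call"
        x
      })
  }
  names(out) <- ids
  out
}

#' @export
print.junction_call <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("junction_call", x$read_id, "- ERROR:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("junction_call %s: %s:%d-%d -> %s (mh=%d, insert=%d bp%s)\n",
              x$read_id, x$proximal$seq_name, x$proximal$ref_start,
              x$proximal$ref_end, x$distal$kind, x$microhomology_len,
              nchar(x$untemplated_insert),
              if (!is.null(x$template_insert)) ", templated insert" else ""))
  invisible(x)
}

#' Serialize junction calls to JSON lines
#'
#' @param calls List of `junction_call`s.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calls_jsonl <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in calls) {
    x <- unclass(cl)
    x$proximal <- if (!is.null(x$proximal)) unclass(x$proximal)
    if (!is.null(x$distal$anchor)) x$distal$anchor <- unclass(x$distal$anchor)
    if (!is.null(x$telomere_array)) x$telomere_array <- unclass(x$telomere_array)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                dataframe = "rows"), con)
  }
  invisible(path)
}
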