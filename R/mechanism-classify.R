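# Repair-mechanism classification: an explicit decision table over the
# evidence in a junction_call.  The table formalizes how junction evidence
# is read in terminal-deletion studies: an adjacent canonical telomere
# array means telomerase-mediated healing; a captured TAR/subtelomeric
# block means telomere capture; a templated (usually inverted) insert means
# FoSTeS/MMBIR; a plain two-anchor junction with modest microhomology and
# insert means NHEJ.  No quantitative thresholds exist in the literature
# for "NHEJ-compatible"; the ceilings here (insert <= 20 bp, microhomology
# <= 10 bp) are explicit formalizations of the observed ranges and are
# configurable.

#' Classify a junction call into a repair mechanism
#'
#' Decision table, first match wins:
#' 1. distal telomere array with canonical units and untemplated gap
#'    <= `gap_max` -> `telomere_healing` (subtype `with_untemplated_insert`
#'    when the gap is non-empty);
#' 2. distal TAR block or foreign subtelomere -> `telomere_capture`;
#' 3. templated insert present (>= `min_template`, either orientation) ->
#'    `FoSTeS_MMBIR`;
#' 4. distal genomic locus with microhomology <= `mh_max` and insert <=
#'    `gap_max` -> `NHEJ`; subtype `ring_candidate` when the distal locus
#'    lies upstream on the same sequence (circularization topology),
#'    `translocation_candidate` on a different sequence, `none` for a
#'    simple (interstitial) deletion;
#' 5. otherwise `unresolved`.
#'
#' Confidence is `low` whenever any anchor is non-unique.  A distal array
#' of pure variant units (non-canonical) is never called healing.
#'
#' @param call A `junction_call`.
#' @param config A [junction_config()] supplying the thresholds.
#' @return A `mechanism_label`: `label`, `subtype`, `evidence` (character
#'   vector), `confidence`.
#' @export
classify_junction <- function(call, config = junction_config()) {
  stopifnot(inherits(call, "junction_call"))
  ev <- character(0)
  low <- FALSE
  if (!is.null(call$error)) {
    return(new_label("unresolved", "none", c(paste("error:", call$error)),
                     "low"))
  }
  if (!is.null(call$proximal) && !isTRUE(call$proximal$unique)) {
    low <- TRUE
    ev <- c(ev, sprintf("proximal anchor ambiguous (%d placements)",
                        call$proximal$ambiguity_count))
  }
  d <- call$distal
  if (!is.null(d$anchor) && !is.null(d$anchor$unique) &&
      !isTRUE(d$anchor$unique)) {
    low <- TRUE
    ev <- c(ev, sprintf("distal anchor ambiguous (%d placements)",
                        d$ambiguity_count))
  }
  conf <- if (low) "low" else "high"
  ins_len <- nchar(call$untemplated_insert)

  if (d$kind == "telomere_array") {
    arr <- d$anchor
    if (isTRUE(arr$canonical) && ins_len <= config$gap_max) {
      ev <- c(ev, sprintf("adjacent telomere array: %d copies (%d canonical)",
                          arr$copies, arr$canonical_copies),
              sprintf("fusion microhomology with GGTTAG: %d bp",
                      call$microhomology_len))
      sub <- if (ins_len > 0L) {
        ev <- c(ev, sprintf("untemplated insert: %d bp", ins_len))
        "with_untemplated_insert"
      } else "direct"
      return(new_label("telomere_healing", sub, ev, conf))
    }
    if (!isTRUE(arr$canonical)) {
      ev <- c(ev, "distal array of non-canonical units; not telomere healing")
      return(new_label("unresolved", "none", ev, conf))
    }
    ev <- c(ev, sprintf("telomere array %d bp past the anchor (> %d)",
                        ins_len, config$gap_max))
    return(new_label("unresolved", "none", ev, conf))
  }

  if (d$kind %in% c("tar_block", "foreign_subtelomere")) {
    sub <- if (d$kind == "tar_block") "tar_capture" else
      "foreign_subtelomere_capture"
    ev <- c(ev, sprintf("distal maps to %s (%s:%d-%d)", d$kind,
                        d$anchor$seq_name, d$anchor$ref_start,
                        d$anchor$ref_end))
    if (!is.null(call$telomere_array)) {
      ev <- c(ev, sprintf("captured block followed by %d telomere units",
                          call$telomere_array$copies))
    }
    return(new_label("telomere_capture", sub, ev, conf))
  }

  if (!is.null(call$template_insert) &&
      diff(call$template_insert$interval) >= config$min_template) {
    ti <- call$template_insert
    ev <- c(ev, sprintf("templated insert %d bp (%s) from deleted interval %s:%d-%d",
                        diff(ti$interval), ti$orientation, ti$seq_name,
                        ti$interval[1], ti$interval[2]),
            sprintf("switch microhomologies %d/%d bp", ti$mh_prox, ti$mh_dist))
    return(new_label("FoSTeS_MMBIR", "none", ev, conf))
  }

  if (d$kind == "genomic_locus" &&
      call$microhomology_len <= config$mh_max && ins_len <= config$gap_max) {
    same <- d$anchor$seq_name == call$proximal$seq_name
    sub <- if (!same) "translocation_candidate"
           else if (d$anchor$ref_start < call$proximal$ref_start) "ring_candidate"
           else "none"
    ev <- c(ev, sprintf("two-anchor junction, microhomology %d bp, insert %d bp",
                        call$microhomology_len, ins_len),
            sprintf("distal locus %s:%d-%d (%s)", d$anchor$seq_name,
                    d$anchor$ref_start, d$anchor$ref_end,
                    if (same) "same sequence" else "different sequence"))
    return(new_label("NHEJ", sub, ev, conf))
  }

  ev <- c(ev, sprintf("distal %s; evidence insufficient", d$kind))
  new_label("unresolved", "none", ev, conf)
}

new_label <- function(label, subtype, evidence, confidence) {
  x <- list(label = label, subtype = subtype, evidence = evidence,
            confidence = confidence)
  class(x) <- "mechanism_label"
  x
}

#' @export
print.mechanism_label <- function(x, ...) {
  cat(sprintf("%s / %s [%s]\n", x$label, x$subtype, x$confidence))
  for (e in x$evidence) cat(" -", e, "\n")
  invisible(x)
}

#' Count mechanism labels by label and subtype
#'
#' @param labels A list of `mechanism_label`s.
#' @return data.frame with `label`, `subtype`, `n`; `sum(n)` equals
#'   `length(labels)`.
#' @export
summarize_mechanisms <- function(labels) {
  lv <- c("telomere_healing", "telomere_capture", "NHEJ", "FoSTeS_MMBIR",
          "unresolved")
  if (length(labels) == 0L) {
    return(data.frame(label = lv, subtype = "none",
                      n = integer(length(lv))))
  }
  lab <- vapply(labels, `[[`, character(1), "label")
  sub <- vapply(labels, `[[`, character(1), "subtype")
  agg <- aggregate(list(n = rep(1L, length(lab))),
                   by = list(label = lab, subtype = sub), FUN = sum)
  agg$label <- factor(agg$label, levels = lv)
  agg <- agg[order(agg$label, agg$subtype), ]
  agg$label <- as.character(agg$label)
  rownames(agg) <- NULL
  agg
}

#' Expected label/subtype for a simulated mechanism
#'
#' Maps a truth mechanism name to the (label, subtype) pair a correct
#' classification yields; used by round-trip evaluations.
#'
#' @param truth A `rearrangement_truth`.
#' @return `list(label, subtype)`; healing subtype depends on whether the
#'   truth carries an untemplated insert, capture subtype on its donor.
#' @export
expected_label <- function(truth) {
  switch(truth$mechanism,
    telomere_healing = list(
      label = "telomere_healing",
      subtype = if (nchar(truth$untemplated_insertion) > 0L)
        "with_untemplated_insert" else "direct"),
    telomere_capture = list(
      label = "telomere_capture",
      subtype = if (identical(truth$source, "tar_block")) "tar_capture"
                else "foreign_subtelomere_capture"),
    nhej_interstitial = list(label = "NHEJ", subtype = "none"),
    ring_junction = list(label = "NHEJ", subtype = "ring_candidate"),
    translocation = list(label = "NHEJ", subtype = "translocation_candidate"),
    fostes_mmbir = list(label = "FoSTeS_MMBIR", subtype = "none"),
    stop("unknown mechanism: ", truth$mechanism, call. = FALSE)
  )
}

#' Write mechanism labels as TSV
#'
#' Columns: `read_id`, `label`, `subtype`, `confidence`, `evidence`
#' (semicolon-joined).
#'
#' @param labels Named list of `mechanism_label`s (names = read ids).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_labels_tsv <- function(labels, path) {
  df <- data.frame(
    read_id = names(labels) %||% seq_along(labels),
    label = vapply(labels, `[[`, character(1), "label"),
    subtype = vapply(labels, `[[`, character(1), "subtype"),
    confidence = vapply(labels, `[[`, character(1), "confidence"),
    evidence = vapply(labels, function(x) paste(x$evidence, collapse = "; "),
                      character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
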