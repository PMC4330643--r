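# Diagnostic annotation: per-sequence states at the cap-binding anchors,
# insertion lengths in the two clade-1 windows, eIF4G-motif scanning at
# murine 68-73, and rule-based clade typing following the residue patterns
# that differentiate the three dinoflagellate clades (Y56/H112 with window
# insertions for clade 1, C112/V162 for clade 2, canonical W56/R112/K162 for
# clade 3, and the metazoan Class II aromatic loss at position 43).

.REPORT_ANCHORS <- c(43L, 46L, 56L, 73L, 102L, 103L, 112L, 157L, 162L, 166L)

.window_insert_len <- function(insertions, row_id, w) {
  rows <- insertions[insertions$row_id == row_id &
                       insertions$after_pos >= w[1] &
                       insertions$after_pos < w[2], , drop = FALSE]
  sum(nchar(rows$segment))
}

#' Diagnostic residue states per sequence
#'
#' For every row of an anchored multiple alignment, reports the residue (or
#' gap) at each diagnostic murine position (43, 46, 56, 73, 102, 103, 112,
#' 157, 162, 166), the summed insertion length inside the W73-W102 and
#' W130-W166 windows, and the C-terminal extension length beyond murine 176
#' (from the untrimmed sequence, when known).
#'
#' @param m A `multi_aln` (or a single `anchored_aln`, trimmed or not).
#' @param anchors [reference_anchors()].
#' @return data.frame of class `residue_report`: seq_id, one `p<pos>` column
#'   per anchor, `ins_73_102`, `ins_130_166`, `cterm_ext`.
#' @export
residue_states <- function(m, anchors = reference_anchors()) {
  if (inherits(m, "anchored_aln")) {
    if (is.null(m$window)) m <- trim_core(m, anchors)
    m <- stack_alignment(list(m))
  }
  stopifnot(inherits(m, "multi_aln"))
  wins <- anchors$insertion_windows
  pos <- .REPORT_ANCHORS
  out <- data.frame(seq_id = m$ids)
  for (p in pos) {
    j <- match(p, m$positions)
    out[[sprintf("p%d", p)]] <-
      if (is.na(j)) "-" else unname(m$matrix[, j])
  }
  out$ins_73_102 <- vapply(m$ids, function(id)
    .window_insert_len(m$insertions, id, wins[[1]]), 0)
  out$ins_130_166 <- vapply(m$ids, function(id)
    .window_insert_len(m$insertions, id, wins[[2]]), 0)
  out$cterm_ext <- unname(m$cterm_ext[m$ids])
  rownames(out) <- NULL
  structure(out, class = c("residue_report", "data.frame"))
}

#' Scan the eIF4G recognition motif
#'
#' Examines murine positions 68-73 (the S/TVxxFW motif ending at W73) and
#' classifies the variant by the charge character of the two variable
#' positions: Q/N polar (the 1a/1b type), D/E acidic (1c type), K/R basic
#' (1d type); a hexamer matching `[ST]V..[FWYL][WFYL]` with uncharged
#' variable positions is `canonical`, anything else `other`.
#'
#' @param m A `multi_aln` or `anchored_aln`.
#' @return data.frame of class `motif_hit`: seq_id, hexamer,
#'   matches_consensus, variant_class.
#' @export
scan_eif4g_motif <- function(m) {
  if (inherits(m, "anchored_aln")) {
    if (is.null(m$window)) m <- trim_core(m)
    m <- stack_alignment(list(m))
  }
  stopifnot(inherits(m, "multi_aln"))
  idx <- match(68:73, m$positions)
  hex <- apply(m$matrix[, idx, drop = FALSE], 1, function(r)
    paste(ifelse(is.na(r), "-", r), collapse = ""))
  matches <- grepl("^[ST]V[A-Z][A-Z][FWYL][WFYL]$", hex)
  third <- substr(hex, 3, 3)
  fourth <- substr(hex, 4, 4)
  cls <- function(a, b, ok) {
    for (x in c(a, b)) {
      if (x %in% c("Q", "N")) return("polar_1a1b")
      if (x %in% c("D", "E")) return("acidic_1c")
      if (x %in% c("K", "R")) return("basic_1d")
    }
    if (ok) "canonical" else "other"
  }
  variant <- mapply(cls, third, fourth, matches)
  out <- data.frame(seq_id = m$ids, hexamer = unname(hex),
                    matches_consensus = unname(matches),
                    variant_class = unname(variant))
  rownames(out) <- NULL
  structure(out, class = c("motif_hit", "data.frame"))
}

#' Rule-based clade typing from diagnostic residues
#'
#' Applies the clade-diagnostic rules in order, first match wins:
#' \enumerate{
#'   \item Y, F or L at position 43: `metazoan_classII_like` (the Class II
#'     aromatic replacement);
#'   \item insertions of at least `min_insert` residues in *both* windows
#'     and H at 112: `clade1_like`;
#'   \item C at 112 and V or A at 162: `clade2_like`;
#'   \item W at 56, R at 112, K at 162 and no window insertion of at least
#'     `min_insert`: `clade3_like`;
#'   \item otherwise `unclassified`.
#' }
#' Sub-clade-level characters (e.g. the W102 to R replacement of 3b) are
#' recorded as evidence but never drive the label: sub-clade resolution
#' belongs to the phylogeny.
#'
#' @param report A `residue_report`.
#' @param motif Optional `motif_hit` table (adds motif evidence).
#' @param min_insert Insertion-length threshold (default 5 residues).
#' @return data.frame of class `diagnostic_class`: seq_id, label, evidence
#'   (semicolon-joined fired rules).
#' @export
classify_diagnostics <- function(report, motif = NULL, min_insert = 5L) {
  stopifnot(inherits(report, "residue_report"))
  n <- nrow(report)
  label <- character(n); evid <- character(n)
  for (i in seq_len(n)) {
    r <- report[i, ]
    ev <- character(0)
    if (r$p43 %in% c("Y", "F", "L")) {
      lab <- "metazoan_classII_like"
      ev <- c(ev, sprintf("W43%s aromatic replacement", r$p43))
    } else if (r$ins_73_102 >= min_insert && r$ins_130_166 >= min_insert &&
               r$p112 == "H") {
      lab <- "clade1_like"
      ev <- c(ev, sprintf("insertions %d aa (73-102) and %d aa (130-166)",
                          r$ins_73_102, r$ins_130_166), "H112")
      if (r$p56 == "Y") ev <- c(ev, "Y56")
      if (r$p162 == "R") ev <- c(ev, "R162")
    } else if (r$p112 == "C" && r$p162 %in% c("V", "A")) {
      lab <- "clade2_like"
      ev <- c(ev, "C112", sprintf("%s162", r$p162))
      if (r$p56 == "Y") ev <- c(ev, "Y56")
    } else if (r$p56 == "W" && r$p112 == "R" && r$p162 == "K" &&
               r$ins_73_102 < min_insert && r$ins_130_166 < min_insert) {
      lab <- "clade3_like"
      ev <- c(ev, "W56", "R112", "K162", "no window insertions")
    } else {
      lab <- "unclassified"
    }
    if (r$p102 == "R") ev <- c(ev, "W102R (3b-type replacement)")
    if (!is.na(r$cterm_ext) && r$cterm_ext >= 100)
      ev <- c(ev, sprintf("C-terminal extension %d aa", r$cterm_ext))
    if (!is.null(motif)) {
      j <- match(r$seq_id, motif$seq_id)
      if (!is.na(j))
        ev <- c(ev, sprintf("eIF4G motif %s (%s)", motif$hexamer[j],
                            motif$variant_class[j]))
    }
    label[i] <- lab
    evid[i] <- paste(ev, collapse = "; ")
  }
  out <- data.frame(seq_id = report$seq_id, label = label, evidence = evid)
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_class", "data.frame"))
}

#' Full annotation table for an alignment
#'
#' Convenience wrapper combining [residue_states()], [scan_eif4g_motif()]
#' and [classify_diagnostics()] into one table per sequence.
#'
#' @param m A `multi_aln`.
#' @param min_insert Passed to [classify_diagnostics()].
#' @return data.frame with anchor states, insertion lengths, motif fields,
#'   diagnostic label and evidence.
#' @export
annotate_alignment <- function(m, min_insert = 5L) {
  rep <- residue_states(m)
  mot <- scan_eif4g_motif(m)
  cls <- classify_diagnostics(rep, mot, min_insert = min_insert)
  out <- cbind(rep,
               mot[match(rep$seq_id, mot$seq_id),
                   c("hexamer", "matches_consensus", "variant_class")],
               cls[match(rep$seq_id, cls$seq_id), c("label", "evidence")])
  rownames(out) <- NULL
  out
}
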