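# Reference-anchored alignment: every surveyed sequence is aligned pairwise
# to the murine eIF4E reference with free end gaps, residues are numbered by
# the murine positions, the alignment is trimmed to the core window (murine
# 38-176) and stacked into a column-consistent multiple alignment in which
# column j *is* murine position j; insertions relative to the reference are
# carried as per-row annotations, never as columns.

#' Align a sequence to the murine eIF4E reference
#'
#' Optimal global alignment with zero-cost terminal gaps (BLOSUM62, affine
#' 11/1), from which a murine numbering map is derived: every residue of the
#' input is assigned either a murine reference position or an insertion code
#' `(after_position, offset)`.
#'
#' @param seq A [seq_record()].
#' @param reference Reference record; defaults to [eif4e_reference()].
#' @param params [search_params()] supplying the scoring parameters.
#' @return Object of class `anchored_aln`: fields `seq_id`, `seq`, `ref_id`,
#'   `map` (data.frame seq_pos, ref_pos, ins_after, ins_offset), `score`,
#'   `window` (NULL until trimmed) and a `partial` flag set when fewer than
#'   half the reference core positions are covered.
#' @examples
#' a <- align_to_reference(eif4e_reference())
#' map_position(a, 102)  # "W"
#' @export
align_to_reference <- function(seq, reference = eif4e_reference(),
                               params = search_params()) {
  stopifnot(inherits(seq, "seq_record"), inherits(reference, "seq_record"))
  if (!nchar(seq$residues)) stop("empty sequence")
  ref_off <- (attr(reference, "offset") %||% 1L) - 1L
  pa <- Biostrings::pairwiseAlignment(
    seq$residues, reference$residues, type = "overlap",
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  qaln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  saln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qstart <- pa@pattern@range@start
  sstart <- pa@subject@range@start
  n <- nchar(seq$residues)
  seq_pos <- integer(0); ref_pos <- integer(0)
  ins_after <- integer(0); ins_offset <- integer(0)
  add <- function(sp, rp, ia, io) {
    seq_pos <<- c(seq_pos, sp); ref_pos <<- c(ref_pos, rp)
    ins_after <<- c(ins_after, ia); ins_offset <<- c(ins_offset, io)
  }
  # leading overhang of the query: insertion after the last reference
  # position preceding the aligned block
  off <- 0L
  for (sp in seq_len(qstart - 1L)) {
    off <- off + 1L
    add(sp, NA_integer_, ref_off + sstart - 1L, off)
  }
  qp <- qstart - 1L
  rp <- sstart - 1L
  off <- 0L
  for (k in seq_along(qaln)) {
    if (saln[k] != "-") { rp <- rp + 1L; off <- 0L }
    if (qaln[k] != "-") {
      qp <- qp + 1L
      if (saln[k] != "-") {
        add(qp, ref_off + rp, NA_integer_, NA_integer_)
      } else {
        off <- off + 1L
        add(qp, NA_integer_, ref_off + rp, off)
      }
    }
  }
  # trailing overhang
  if (qp < n) {
    off <- if (length(ins_offset) && !is.na(ins_after[length(ins_after)]) &&
               ins_after[length(ins_after)] == ref_off + rp)
      ins_offset[length(ins_offset)] else 0L
    for (sp in seq.int(qp + 1L, n)) {
      off <- off + 1L
      add(sp, NA_integer_, ref_off + rp, off)
    }
  }
  map <- data.frame(seq_pos = seq_pos, ref_pos = ref_pos,
                    ins_after = ins_after, ins_offset = ins_offset)
  anch <- reference_anchors()
  core <- anch$positions
  covered <- sum(!is.na(map$ref_pos) & map$ref_pos %in% core)
  structure(list(seq_id = seq$id, seq = seq, ref_id = reference$id,
                 map = map, score = Biostrings::score(pa), window = NULL,
                 partial = covered < length(core) / 2),
            class = "anchored_aln")
}

#' @export
print.anchored_aln <- function(x, ...) {
  cat(sprintf("anchored_aln %s -> %s: %d residues, %d mapped, %d inserted%s%s\n",
              x$seq_id, x$ref_id, nrow(x$map), sum(!is.na(x$map$ref_pos)),
              sum(is.na(x$map$ref_pos)),
              if (!is.null(x$window))
                sprintf(", trimmed to %d-%d", x$window[1], x$window[2]) else "",
              if (isTRUE(x$partial)) " [partial]" else ""))
  invisible(x)
}

#' Trim an anchored alignment to the eIF4E core window
#'
#' Retains residues mapping to murine positions 38-176 (five upstream of
#' W43 through ten downstream of W166) together with insertions anchored
#' inside the window.
#'
#' @param a An `anchored_aln`.
#' @param anchors [reference_anchors()].
#' @return The trimmed `anchored_aln` (window field set). The C-terminal
#'   extension length beyond the window is recorded in field `cterm_ext`.
#' @export
trim_core <- function(a, anchors = reference_anchors()) {
  stopifnot(inherits(a, "anchored_aln"))
  lo <- anchors$core_start; hi <- anchors$core_end
  m <- a$map
  keep <- (!is.na(m$ref_pos) & m$ref_pos >= lo & m$ref_pos <= hi) |
    (is.na(m$ref_pos) & !is.na(m$ins_after) &
       m$ins_after >= lo & m$ins_after < hi)
  if (!any(keep & !is.na(m$ref_pos)))
    stop(sprintf("no core domain: '%s' has no residue mapped in %d-%d",
                 a$seq_id, lo, hi))
  a$cterm_ext <- sum((!is.na(m$ref_pos) & m$ref_pos > hi) |
                       (is.na(m$ref_pos) & !is.na(m$ins_after) &
                          m$ins_after >= hi))
  a$map <- m[keep, , drop = FALSE]
  rownames(a$map) <- NULL
  a$window <- c(lo, hi)
  a
}

#' Residue at a murine reference position
#'
#' @param a An `anchored_aln`.
#' @param murine_pos Position on the murine reference, inside the core
#'   window (38-176).
#' @return Single residue character, or `"-"` when unmapped.
#' @export
map_position <- function(a, murine_pos) {
  stopifnot(inherits(a, "anchored_aln"))
  anch <- reference_anchors()
  if (murine_pos < anch$core_start || murine_pos > anch$core_end)
    stop(sprintf("position %d outside the core window %d-%d",
                 murine_pos, anch$core_start, anch$core_end))
  i <- which(!is.na(a$map$ref_pos) & a$map$ref_pos == murine_pos)
  if (!length(i)) return("-")
  substr(a$seq$residues, a$map$seq_pos[i], a$map$seq_pos[i])
}

#' Stack trimmed anchored alignments into a multiple alignment
#'
#' Builds the column-consistent multiple alignment over the 139 murine core
#' positions: column j corresponds to murine position j (gap where a row has
#' no residue mapped there); insertions are stored per row as
#' `(after_position, segment)` records and do not create columns, so match
#' columns are invariant to adding or removing rows.
#'
#' @param alns List of trimmed `anchored_aln` objects (same window).
#' @return Object of class `multi_aln`: `ids`, character `matrix` (rows x
#'   139 columns named by murine position), `insertions` data.frame
#'   (row_id, after_pos, segment), `positions`, and per-row `cterm_ext`.
#' @export
stack_alignment <- function(alns) {
  stopifnot(length(alns) >= 1)
  ids <- vapply(alns, `[[`, "", "seq_id")
  if (anyDuplicated(ids))
    stop("duplicate row id: ", ids[duplicated(ids)][1])
  windows <- lapply(alns, `[[`, "window")
  if (any(vapply(windows, is.null, TRUE)))
    stop("all alignments must be trimmed (see trim_core)")
  w <- windows[[1]]
  if (!all(vapply(windows, function(x) identical(x, w), TRUE)))
    stop("alignments trimmed to different windows")
  positions <- seq.int(w[1], w[2])
  mat <- matrix("-", length(alns), length(positions),
                dimnames = list(ids, positions))
  ins <- list()
  cterm <- numeric(length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    m <- a$map
    mapped <- !is.na(m$ref_pos)
    res <- strsplit(a$seq$residues, "")[[1]]
    mat[i, match(m$ref_pos[mapped], positions)] <- res[m$seq_pos[mapped]]
    if (any(!mapped)) {
      by_after <- split(m$seq_pos[!mapped], m$ins_after[!mapped])
      for (ap in names(by_after)) {
        seg <- paste(res[sort(by_after[[ap]])], collapse = "")
        ins[[length(ins) + 1L]] <-
          data.frame(row_id = ids[i], after_pos = as.integer(ap),
                     segment = seg)
      }
    }
    cterm[i] <- a$cterm_ext %||% NA_real_
  }
  insertions <- if (length(ins)) do.call(rbind, ins) else
    data.frame(row_id = character(0), after_pos = integer(0),
               segment = character(0))
  structure(list(ids = ids, matrix = mat, insertions = insertions,
                 positions = positions,
                 cterm_ext = stats::setNames(cterm, ids)),
            class = "multi_aln")
}

#' @export
print.multi_aln <- function(x, ...) {
  cat(sprintf("multi_aln: %d rows x %d match columns (positions %d-%d), %d insertion records\n",
              length(x$ids), length(x$positions), min(x$positions),
              max(x$positions), nrow(x$insertions)))
  invisible(x)
}

#' Coerce gapped rows to a multiple alignment
#'
#' Turns equal-length gapped strings (e.g. a deposited NEXUS matrix) into a
#' `multi_aln` whose columns are numbered 1..L and which carries no
#' insertion records. This is the entry point for externally aligned data.
#'
#' @param x Named character vector of gapped rows, or a character matrix
#'   with row names.
#' @param positions Optional integer column labels (defaults to 1..L).
#' @return A `multi_aln`.
#' @export
as_multi_alignment <- function(x, positions = NULL) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    if (length(unique(nchar(x))) != 1) stop("rows differ in length")
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  }
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  stopifnot(length(positions) == ncol(mat))
  mat[mat == "."] <- "-"
  colnames(mat) <- positions
  structure(list(ids = rownames(mat), matrix = mat,
                 insertions = data.frame(row_id = character(0),
                                         after_pos = integer(0),
                                         segment = character(0)),
                 positions = as.integer(positions),
                 cterm_ext = stats::setNames(rep(NA_real_, nrow(mat)),
                                             rownames(mat))),
            class = "multi_aln")
}

# rows of a multi_aln as gapped strings
.aln_rows <- function(m, ids = NULL) {
  stopifnot(inherits(m, "multi_aln"))
  mat <- m$matrix
  if (!is.null(ids)) mat <- mat[ids, , drop = FALSE]
  apply(mat, 1, paste, collapse = "")
}

#' Write a multiple alignment as gapped FASTA
#'
#' Emits the match-column matrix (insertions are not written; they live in
#' the numbering map).
#'
#' @param m A `multi_aln`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(m, path) {
  rows <- .aln_rows(m)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rows)) {
    writeLines(paste0(">", id), con)
    writeLines(rows[[id]], con)
  }
  invisible(path)
}

#' Numbering map as a table
#'
#' One row per sequence residue: `seq_pos` (1-based), and either the murine
#' position or an insertion code `after.offset`.
#'
#' @param a An `anchored_aln`.
#' @return data.frame with columns seq_id, seq_pos, murine_pos_or_insert.
#' @export
numbering_table <- function(a) {
  stopifnot(inherits(a, "anchored_aln"))
  m <- a$map
  lab <- ifelse(!is.na(m$ref_pos), as.character(m$ref_pos),
                sprintf("%d.%d", m$ins_after, m$ins_offset))
  data.frame(seq_id = a$seq_id, seq_pos = m$seq_pos,
             murine_pos_or_insert = lab)
}
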