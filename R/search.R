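# Family census: exact local alignment (Smith-Waterman via Biostrings) with
# Karlin-Altschul E-values, and the iterative query-expanding census with the
# survey's acceptance rules (E <= 1e-10 and >= 130 aligned residues).

#' Census search parameters
#'
#' Acceptance thresholds and scoring parameters for the family census. The
#' defaults are the survey's: E-value cutoff 1e-10, minimum 130 aligned
#' residues, BLOSUM62 with affine gap penalties 11/1, and the gapped
#' Karlin-Altschul parameters lambda = 0.267, K = 0.041.
#'
#' @param evalue_cutoff Maximum E-value for acceptance (> 0).
#' @param min_aligned_length Minimum number of alignment columns (>= 1).
#' @param gap_open,gap_extend Affine gap penalties (open >= extend > 0); a
#'   gap of length L costs `gap_open + L * gap_extend`.
#' @param scoring_matrix Name of the scoring matrix (only `"BLOSUM62"`).
#' @param lambda,K Karlin-Altschul statistics for the E-value formula
#'   `E = K * m * n * exp(-lambda * S)`.
#' @return Object of class `search_params`.
#' @export
search_params <- function(evalue_cutoff = 1e-10, min_aligned_length = 130L,
                          gap_open = 11, gap_extend = 1,
                          scoring_matrix = "BLOSUM62",
                          lambda = 0.267, K = 0.041) {
  stopifnot(evalue_cutoff > 0, min_aligned_length >= 1,
            gap_open >= gap_extend, gap_extend > 0,
            identical(scoring_matrix, "BLOSUM62"),
            lambda > 0, K > 0)
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_aligned_length = as.integer(min_aligned_length),
                 gap_open = gap_open, gap_extend = gap_extend,
                 scoring_matrix = scoring_matrix,
                 lambda = lambda, K = K),
            class = "search_params")
}

.subst_matrix <- function(params) blosum62(x_zero = TRUE)

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `score`:
#' `E = K * m * n * exp(-lambda * S)`, strictly decreasing in the score and
#' linear in the database size, so that the census's 1e-10 cutoff has its
#' usual meaning.
#'
#' @param score Raw alignment score (>= 0).
#' @param query_len Query length m (>= 1).
#' @param db_residues Total database residues n (>= 1).
#' @param params [search_params()].
#' @return E-value (numeric).
#' @examples
#' evalue(0, 100, 100)  # K * 1e4 = 410 with defaults
#' @export
evalue <- function(score, query_len, db_residues, params = search_params()) {
  stopifnot(score >= 0, query_len >= 1, db_residues >= 1)
  params$K * query_len * db_residues * exp(-params$lambda * score)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps under BLOSUM62 (X scoring
#' 0 against everything). Returns `NULL` when the optimal local score is 0,
#' i.e. no positively scoring segment pair exists.
#'
#' @param query,subject [seq_record()] objects (non-empty).
#' @param params [search_params()].
#' @param db_residues Database size used for the E-value; defaults to the
#'   subject length (single-sequence database).
#' @return A `local_hit` (list with query_id, subject_id, score, evalue,
#'   aligned_length and 0-based half-open `query_span` / `subject_span`), or
#'   `NULL`.
#' @examples
#' w <- seq_record("w", "WWWWW")
#' local_align(w, w)$score  # 55 = 5 * BLOSUM62[W,W]
#' @export
local_align <- function(query, subject, params = search_params(),
                        db_residues = NULL) {
  stopifnot(inherits(query, "seq_record"), inherits(subject, "seq_record"))
  if (!nchar(query$residues) || !nchar(subject$residues)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    query$residues, subject$residues, type = "local",
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  .hit_from_alignment(pa, query, subject,
                      db_residues %||% nchar(subject$residues), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hit_from_alignment <- function(pa, query, subject, db_residues, params) {
  s <- Biostrings::score(pa)
  if (s <= 0) return(NULL)
  paln <- as.character(Biostrings::alignedPattern(pa))
  alen <- nchar(paln)
  qr <- pa@pattern@range
  sr <- pa@subject@range
  structure(list(query_id = query$id, subject_id = subject$id,
                 score = s,
                 evalue = evalue(s, nchar(query$residues), db_residues,
                                 params),
                 aligned_length = alen,
                 query_span = c(qr@start - 1L, qr@start + qr@width - 1L),
                 subject_span = c(sr@start - 1L, sr@start + sr@width - 1L)),
            class = "local_hit")
}

#' @export
print.local_hit <- function(x, ...) {
  cat(sprintf("%s ~ %s  score %.0f  E %.3g  %d cols  q[%d,%d) s[%d,%d)\n",
              x$query_id, x$subject_id, x$score, x$evalue, x$aligned_length,
              x$query_span[1], x$query_span[2],
              x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

#' Iterative query-expanding family census
#'
#' Runs the survey's iterative homology search: every seed query is aligned
#' against every database sequence; subjects passing both acceptance rules
#' (E-value at most the cutoff against the pooled database size, and at
#' least `min_aligned_length` aligned columns) join the census *and* the
#' query set, and the process repeats until no novel members are found. The
#' result is the fixpoint of the acceptance relation and is deterministic
#' given input order; `round_found` records the iteration of first
#' acceptance.
#'
#' @param seed_queries `seq_set` (or list of records) of starting queries.
#' @param databases A single `seq_set` or a list of them (per species or per
#'   assembly); duplicate ids across databases are collapsed to their first
#'   occurrence.
#' @param params [search_params()].
#' @param max_rounds Safety bound on iterations.
#' @return A `census_table`: data.frame with columns member_id, species,
#'   group, best_query, score, evalue, aligned_length, round_found.
#' @export
iterative_census <- function(seed_queries, databases,
                             params = search_params(), max_rounds = 50L) {
  if (inherits(databases, "seq_set")) databases <- list(databases)
  if (inherits(seed_queries, "seq_record")) seed_queries <- list(seed_queries)
  if (!length(seed_queries)) stop("at least one seed query is required")
  pool <- list()
  for (db in databases)
    for (r in db) if (is.null(pool[[r$id]])) pool[[r$id]] <- r
  db_residues <- sum(vapply(pool, function(r) nchar(r$residues), 0L))
  db_residues <- max(db_residues, 1L)
  mat <- .subst_matrix(params)

  remaining <- pool
  rows <- list()
  queries <- seed_queries            # queries to run this round
  round <- 0L
  while (length(queries) && length(remaining) && round < max_rounds) {
    round <- round + 1L
    accepted_ids <- character(0)
    best <- list()                   # subject_id -> best passing hit
    for (q in queries) {
      if (!length(remaining)) break
      if (!nchar(q$residues)) next
      subj <- vapply(remaining, `[[`, "", "residues")
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::BStringSet(subj), q$residues, type = "local",
        substitutionMatrix = mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      sc <- Biostrings::score(pa)
      alen <- nchar(as.character(Biostrings::alignedSubject(pa)))
      ev <- evalue(pmax(sc, 0), nchar(q$residues), db_residues, params)
      pass <- sc > 0 & ev <= params$evalue_cutoff &
        alen >= params$min_aligned_length
      for (i in which(pass)) {
        sid <- names(remaining)[i]
        if (is.null(best[[sid]]) || sc[i] > best[[sid]]$score) {
          best[[sid]] <- list(query_id = q$id, score = sc[i],
                              evalue = ev[i], aligned_length = alen[i])
        }
      }
    }
    accepted_ids <- names(best)
    if (!length(accepted_ids)) break
    for (sid in accepted_ids) {
      r <- remaining[[sid]]
      h <- best[[sid]]
      rows[[sid]] <- data.frame(member_id = sid, species = r$species,
                                group = r$group, best_query = h$query_id,
                                score = h$score, evalue = h$evalue,
                                aligned_length = h$aligned_length,
                                round_found = round)
    }
    queries <- remaining[accepted_ids]   # novel members become queries
    remaining <- remaining[setdiff(names(remaining), accepted_ids)]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(member_id = character(0), species = character(0),
               group = character(0), best_query = character(0),
               score = numeric(0), evalue = numeric(0),
               aligned_length = integer(0), round_found = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("census_table", "data.frame"),
            params = params, n_database = length(pool),
            db_residues = db_residues, n_rounds = round)
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("eIF4E family census: %d members (of %d database sequences, %d rounds)\n",
              nrow(x), attr(x, "n_database") %||% NA_integer_,
              attr(x, "n_rounds") %||% NA_integer_))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @method summary census_table
#' @export
summary.census_table <- function(object, ...) census_summary(object, ...)
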