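# Alignment statistics: per-row amino-acid composition chi-squared tests
# against the pooled alignment frequencies (the Tree-Puzzle convention),
# pairwise percent identity, within-group column variability, and
# sequence-logo information content with the small-sample correction.
# Gaps and X are excluded from all counts.

.row_chars <- function(x) {
  if (inherits(x, "multi_aln")) {
    rows <- x$matrix
  } else if (is.matrix(x)) {
    rows <- x
  } else {
    stopifnot(is.character(x))
    if (is.null(names(x))) names(x) <- paste0("row", seq_along(x))
    if (length(unique(nchar(x))) != 1) stop("rows differ in length")
    rows <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(rows) <- names(x)
  }
  rows
}

#' Composition-bias chi-squared test per alignment row
#'
#' Compares each row's amino-acid composition with the empirical
#' frequencies pooled over the whole alignment: for row i with non-gap
#' count N and residue counts n_a, the expected counts are e_a = N * f_a
#' over residues with pooled frequency f_a > 0, and the statistic is
#' sum((n_a - e_a)^2 / e_a). Cells with expected count below 1 are pooled
#' into a single rare-residue cell (df reduced accordingly). Rows are
#' flagged at level `alpha`.
#'
#' @param m A `multi_aln`, character matrix, or vector of gapped rows.
#' @param alpha Flagging level (default 0.05, the conventional 5% level).
#' @return data.frame of class `composition_test`: seq_id, n, chi2, df,
#'   p_value, flagged.
#' @export
composition_chi2 <- function(m, alpha = 0.05) {
  rows <- .row_chars(m)
  if (nrow(rows) < 2) stop("composition test needs at least 2 rows")
  aa <- aa_alphabet()
  counts <- t(apply(rows, 1, function(r) table(factor(r, levels = aa))))
  pooled <- colSums(counts)
  f <- pooled / sum(pooled)
  live <- which(f > 0)
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    N <- sum(counts[i, ])
    if (N == 0) {
      warning("row '", rownames(rows)[i], "' has no residues; skipped")
      next
    }
    obs <- counts[i, live]
    exp_ <- N * f[live]
    pool <- exp_ < 1
    if (any(pool)) {
      obs <- c(obs[!pool], sum(obs[pool]))
      exp_ <- c(exp_[!pool], sum(exp_[pool]))
    }
    chi2 <- sum((obs - exp_)^2 / exp_)
    df <- length(exp_) - 1L
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    out[[i]] <- data.frame(seq_id = rownames(rows)[i], n = N, chi2 = chi2,
                           df = df, p_value = p, flagged = p < alpha)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out, class = c("composition_test", "data.frame"),
            alpha = alpha, pooled_frequencies = f)
}

#' Percent identity of two gapped rows
#'
#' 100 x matches / mutually non-gap columns (X counts as missing).
#'
#' @param a,b Gapped row strings of equal length.
#' @return Identity in [0, 100].
#' @examples
#' percent_identity("AC-DE", "AXFDE")  # 3 comparable columns, all equal
#' @export
percent_identity <- function(a, b) {
  ra <- strsplit(toupper(a), "")[[1]]
  rb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ra) == length(rb))
  ok <- !(ra %in% c("-", ".", "X")) & !(rb %in% c("-", ".", "X"))
  if (!any(ok)) stop("no mutually non-gap columns")
  100 * sum(ra[ok] == rb[ok]) / sum(ok)
}

#' Whole-sequence percent identity of two unaligned records
#'
#' Aligns the untrimmed sequences globally (free end gaps, BLOSUM62 11/1)
#' and computes identity over the mutually non-gap columns: the
#' "across the entire sequence" comparison, as opposed to the core-region
#' identity of [percent_identity()] on alignment rows.
#'
#' @param a,b [seq_record()] objects.
#' @param params [search_params()] for the scoring parameters.
#' @return Identity in [0, 100].
#' @export
percent_identity_full <- function(a, b, params = search_params()) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  pa <- Biostrings::pairwiseAlignment(
    a$residues, b$residues, type = "overlap",
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  percent_identity(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa)))
}

#' Proportion of variable columns
#'
#' 100 x (columns with at least two distinct non-gap residues) / (columns
#' with at least two non-gap residues). A column with one residue plus gaps
#' is not counted on either side.
#'
#' @param x Rows of a group (as for [composition_chi2()]).
#' @return Percentage in [0, 100].
#' @export
column_variability <- function(x) {
  rows <- .row_chars(x)
  if (nrow(rows) < 2) stop("variability needs at least 2 rows")
  aa <- aa_alphabet()
  comparable <- 0L; variable <- 0L
  for (j in seq_len(ncol(rows))) {
    col <- rows[, j]
    col <- col[col %in% aa]
    if (length(col) >= 2) {
      comparable <- comparable + 1L
      if (length(unique(col)) >= 2) variable <- variable + 1L
    }
  }
  if (comparable == 0) return(0)
  100 * variable / comparable
}

#' Sequence-logo information content matrix
#'
#' Per match column: Shannon entropy H over non-gap residues, small-sample
#' correction e_n = 19 / (2 ln 2 n), total information
#' R = max(0, log2 20 - H - e_n) bits, and letter heights p_a * R. With a
#' single sequence the correction exceeds log2 20, so R clamps to 0; for an
#' invariant column R tends to log2 20 (~4.32 bits) as n grows.
#'
#' @param x Rows of a group (as for [composition_chi2()]).
#' @return data.frame of class `logo_matrix`: position, n_nongap, R_bits,
#'   then one height column per residue.
#' @export
logo_matrix <- function(x) {
  rows <- .row_chars(x)
  aa <- aa_alphabet()
  positions <- colnames(rows)
  if (is.null(positions)) positions <- as.character(seq_len(ncol(rows)))
  out <- data.frame(position = positions, n_nongap = 0L, R_bits = 0)
  heights <- matrix(0, ncol(rows), 20, dimnames = list(NULL, aa))
  for (j in seq_len(ncol(rows))) {
    col <- rows[, j]
    col <- col[col %in% aa]
    n <- length(col)
    out$n_nongap[j] <- n
    if (n == 0) next
    p <- as.numeric(table(factor(col, levels = aa))) / n
    H <- -sum(p[p > 0] * log2(p[p > 0]))
    en <- 19 / (2 * log(2) * n)
    R <- max(0, log2(20) - H - en)
    out$R_bits[j] <- R
    heights[j, ] <- p * R
  }
  out <- cbind(out, heights)
  rownames(out) <- NULL
  structure(out, class = c("logo_matrix", "data.frame"))
}

#' @method plot logo_matrix
#' @export
plot.logo_matrix <- function(x, ...) {
  h <- t(as.matrix(x[, aa_alphabet()]))
  graphics::barplot(h, names.arg = x$position, las = 2, border = NA,
                    col = grDevices::hcl.colors(20, "Spectral"),
                    ylab = "information (bits)", ...)
  invisible(x)
}

#' Pairwise identity table for sub-clades
#'
#' Long-format table of within-sub-clade pairwise core identities, the
#' quantity used to rank sub-clade conservation.
#'
#' @param m A `multi_aln`.
#' @param partition A `clade_partition` with sub-clades.
#' @return data.frame: subclade, id_a, id_b, identity.
#' @export
subclade_identity_table <- function(m, partition) {
  rows <- .aln_rows(m)
  out <- list()
  for (sc in partition$subclades) {
    ids <- intersect(sc$leaves, names(rows))
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        out[[length(out) + 1L]] <-
          data.frame(subclade = sc$name, id_a = ids[i], id_b = ids[j],
                     identity = tryCatch(
                       percent_identity(rows[[ids[i]]], rows[[ids[j]]]),
                       error = function(e) NA_real_))
      }
    }
  }
  if (!length(out))
    return(data.frame(subclade = character(0), id_a = character(0),
                      id_b = character(0), identity = numeric(0)))
  do.call(rbind, out)
}
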