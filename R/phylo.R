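# Distance-based phylogeny over the 139 match columns: pairwise protein
# distances (Poisson, Kimura, or 1-D maximum likelihood under LG+Gamma),
# neighbor-joining with negative-branch clamping, and nonparametric column
# bootstrap with bipartition support. This distance stage is the desk-scale
# stand-in for a full ML topology search: bootstrap percentages from the
# published 1000-replicate ML analysis are not expected to be matched.

.KIMURA_CAP <- 5.2

#' Pairwise distance between two alignment rows
#'
#' Distances are computed over mutually non-gap match columns (X counts as
#' missing). `poisson` is `-ln(1 - p)`; `kimura` is the gamma-corrected
#' approximation `-ln(1 - p - 0.2 p^2)`, set to a cap of 5.2 (with a
#' warning) where the argument of the logarithm is non-positive
#' (p >= 0.8541); `lg_ml` maximises the two-sequence likelihood under the
#' supplied substitution model over the branch length.
#'
#' @param a,b Gapped row strings (equal length).
#' @param method `"kimura"` (default), `"poisson"` or `"lg_ml"`.
#' @param model [substitution_model()], used by `lg_ml`.
#' @return Non-negative distance (expected substitutions per site).
#' @examples
#' pairwise_distance("AAAA", "AAAC")  # p = 0.25
#' @export
pairwise_distance <- function(a, b, method = c("kimura", "poisson", "lg_ml"),
                              model = NULL) {
  method <- match.arg(method)
  ra <- strsplit(toupper(a), "")[[1]]
  rb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ra) == length(rb))
  ok <- !(ra %in% c("-", "X", ".")) & !(rb %in% c("-", "X", "."))
  n <- sum(ok)
  if (n == 0) stop("no mutually non-gap columns")
  p <- sum(ra[ok] != rb[ok]) / n
  if (method == "poisson") {
    if (p >= 1) return(.KIMURA_CAP)
    return(-log(1 - p))
  }
  if (method == "kimura") {
    arg <- 1 - p - 0.2 * p^2
    if (arg <= 0) {
      warning(sprintf("kimura distance undefined at p = %.3f; capped at %g",
                      p, .KIMURA_CAP))
      return(.KIMURA_CAP)
    }
    return(-log(arg))
  }
  # lg_ml: 1-D ML branch length for the two-row alignment
  if (is.null(model)) model <- substitution_model("LG")
  if (p == 0) return(0)
  ia <- match(ra[ok], aa_alphabet())
  ib <- match(rb[ok], aa_alphabet())
  # likelihood per site: mean over rate categories of pi_a * P_ab(t r)
  nll <- function(t) {
    k <- length(model$rates)
    sitelik <- rep(0, n)
    for (r in model$rates) {
      P <- transition_prob(model, t * r)
      sitelik <- sitelik + model$pi[ia] * P[cbind(ia, ib)] / k
    }
    -sum(log(pmax(sitelik, 1e-300)))
  }
  stats::optimize(nll, c(1e-8, 20))$minimum
}

#' Distance matrix over a multiple alignment
#'
#' @param m A `multi_aln`.
#' @param method,model Passed to [pairwise_distance()].
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
distance_matrix <- function(m, method = c("kimura", "poisson", "lg_ml"),
                            model = NULL) {
  method <- match.arg(method)
  if (method == "lg_ml" && is.null(model)) model <- substitution_model("LG")
  rows <- .aln_rows(m)
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        pairwise_distance(rows[[i]], rows[[j]], method, model)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (via ape), followed by clamping of
#' negative branch lengths to zero with the deficit moved onto the sister
#' edge, so the tree's path lengths are preserved where possible.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor-joining requires at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sisters))
      tr$edge.length[sisters[1]] <-
        max(0, tr$edge.length[sisters[1]] + deficit)
  }
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the tree from the full set of match columns, then resamples the
#' match columns with replacement `B` times (insertions are never part of
#' the column set), rebuilds a tree per replicate, and annotates every
#' internal bipartition of the best tree with the percentage of replicates
#' containing it.
#'
#' @param m A `multi_aln`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the run is reproducible for a fixed seed.
#' @param method,model Distance options, as [pairwise_distance()].
#' @return A `tree_support` object: `phylo` whose `node.label` holds
#'   supports in [0, 100] (root NA), with attribute `n_replicates`.
#' @export
bootstrap_support <- function(m, B = 100L, seed = 1L,
                              method = c("kimura", "poisson", "lg_ml"),
                              model = NULL) {
  stopifnot(inherits(m, "multi_aln"), B >= 1)
  method <- match.arg(method)
  if (method == "lg_ml" && is.null(model)) model <- substitution_model("LG")
  best <- nj_tree(distance_matrix(m, method, model))
  ncol_m <- ncol(m$matrix)
  boots <- withr_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(ncol_m, ncol_m, replace = TRUE)
      mb <- m
      mb$matrix <- m$matrix[, idx, drop = FALSE]
      tryCatch(nj_tree(distance_matrix(mb, method, model)),
               error = function(e) NULL)
    })
  })
  boots <- boots[!vapply(boots, is.null, TRUE)]
  counts <- ape::prop.clades(best, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / max(length(boots), 1L), 1)
  best$node.label <- as.character(support)
  structure(best, n_replicates = as.integer(B),
            class = c("tree_support", "phylo"))
}

# evaluate expr with a local RNG seed, restoring global state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.tree_support <- function(x, ...) {
  cat(sprintf("NJ tree with %d tips, bootstrap support from %d replicates\n",
              length(x$tip.label), attr(x, "n_replicates")))
  sup <- suppressWarnings(as.numeric(x$node.label))
  sup <- sup[!is.na(sup)]
  if (length(sup))
    cat(sprintf("support: median %.0f%%, %d/%d bipartitions >= 55%%\n",
                stats::median(sup), sum(sup >= 55), length(sup)))
  invisible(x)
}
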