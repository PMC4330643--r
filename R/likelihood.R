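# Fixed-topology likelihood scoring: Felsenstein pruning over the match
# columns under a reversible empirical amino-acid model with discrete-gamma
# rates, gaps treated as missing data. Used for the model-frequency
# comparison (model vs empirical frequencies) and for gamma-shape
# estimation on a fixed topology; there is no topology search here.

# encode alignment rows as integer indices (NA = gap/missing)
.encode_rows <- function(m, tips) {
  rows <- .aln_rows(m, tips)
  aa <- aa_alphabet()
  lapply(rows, function(s) {
    v <- match(strsplit(s, "")[[1]], aa)
    v
  })
}

#' Log-likelihood of a fixed tree under a substitution model
#'
#' Felsenstein pruning over the match columns of an alignment: per-site
#' likelihoods are averaged over the model's discrete-gamma rate categories
#' and log-summed. Gaps and X are treated as missing data (partial
#' likelihood 1 for every residue). Site patterns are compressed before
#' computation. By time-reversibility the result is invariant to the
#' placement of the root (pulley principle).
#'
#' @param tree `phylo` with branch lengths; its tips must all be rows of
#'   `m`.
#' @param m A `multi_aln` (or object coercible via [as_multi_alignment()]).
#' @param model A [substitution_model()].
#' @return Summed log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, m, model = substitution_model("LG")) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"))
  if (!inherits(m, "multi_aln")) m <- as_multi_alignment(m)
  missing_tips <- setdiff(tree$tip.label, m$ids)
  if (length(missing_tips))
    stop("tree leaf without alignment row: ", missing_tips[1])
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  codes <- .encode_rows(m, tree$tip.label)
  # site-pattern compression
  patt_mat <- do.call(rbind, codes)               # ntip x S
  key <- apply(patt_mat, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[uniq])))
  patt <- patt_mat[, uniq, drop = FALSE]
  S <- ncol(patt)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  sitelik <- rep(0, S)
  for (r in model$rates) {
    partial <- vector("list", nnode)
    for (tip in seq_len(ntip)) {
      L <- matrix(1, 20, S)
      v <- patt[tip, ]
      obs <- which(!is.na(v))
      if (length(obs)) {
        L[, obs] <- 0
        L[cbind(v[obs], obs)] <- 1
      }
      partial[[tip]] <- L
    }
    for (e in seq_len(nrow(tr$edge))) {
      child <- tr$edge[e, 2]
      parent <- tr$edge[e, 1]
      P <- transition_prob(model, tr$edge.length[e] * r)
      msg <- P %*% partial[[child]]
      if (is.null(partial[[parent]])) partial[[parent]] <- msg
      else partial[[parent]] <- partial[[parent]] * msg
    }
    sitelik <- sitelik +
      as.vector(model$pi %*% partial[[root]]) / length(model$rates)
  }
  sum(weights * log(pmax(sitelik, 1e-300)))
}

#' Estimate the gamma shape on a fixed topology
#'
#' One-dimensional bounded search for the discrete-gamma shape alpha
#' maximising [tree_log_likelihood()] with the tree and all other model
#' parameters held fixed.
#'
#' @param tree `phylo` with branch lengths.
#' @param m A `multi_aln`.
#' @param model Base [substitution_model()] (its shape is ignored).
#' @param bounds Search interval for alpha (default 0.05-10).
#' @return List with `alpha` and `logLik`.
#' @export
estimate_gamma_shape <- function(tree, m, model = substitution_model("LG"),
                                 bounds = c(0.05, 10)) {
  f <- function(a) {
    mod <- model
    mod$gamma_shape <- a
    mod$rates <- discrete_gamma_rates(a, model$n_categories)
    -tree_log_likelihood(tree, m, mod)
  }
  opt <- stats::optimize(f, bounds)
  list(alpha = opt$minimum, logLik = -opt$objective)
}

#' Compare model frequencies against empirical alignment frequencies
#'
#' Scores a fixed tree twice under the same exchangeability matrix: once
#' with the matrix's own published frequencies and once with the empirical
#' amino-acid frequencies of the alignment (non-gap residues, floored and
#' renormalised). This is the model-selection comparison used to choose LG
#' frequencies for the family phylogeny.
#'
#' @param tree `phylo` with branch lengths.
#' @param m A `multi_aln`.
#' @param name Exchangeability matrix name (default `"LG"`).
#' @param gamma_shape,n_categories Gamma settings shared by both fits.
#' @return List with `logLik_model`, `logLik_empirical`,
#'   `model_preferred` (logical) and the two frequency vectors.
#' @export
compare_frequencies <- function(tree, m, name = "LG", gamma_shape = 1,
                                n_categories = 4L) {
  mod <- substitution_model(name, gamma_shape, n_categories, "model")
  emp <- empirical_frequencies(m)
  mod_emp <- substitution_model(name, gamma_shape, n_categories, emp)
  ll_mod <- tree_log_likelihood(tree, m, mod)
  ll_emp <- tree_log_likelihood(tree, m, mod_emp)
  list(logLik_model = ll_mod, logLik_empirical = ll_emp,
       model_preferred = ll_mod >= ll_emp,
       freq_model = mod$pi, freq_empirical = mod_emp$pi)
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Frequencies pooled over all non-gap, non-X residues of the match
#' columns.
#'
#' @param m A `multi_aln`.
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
empirical_frequencies <- function(m) {
  stopifnot(inherits(m, "multi_aln"))
  counts <- table(factor(m$matrix, levels = aa_alphabet()))
  f <- as.numeric(counts)
  names(f) <- aa_alphabet()
  f / sum(f)
}
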