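# Packaged reference data: the murine eIF4E-1 sequence with its canonical
# residue numbering, the cap-binding / eIF4G anchor set, the BLOSUM62 scoring
# matrix, and empirical amino-acid substitution models (LG, WAG, JTT).

# Murine eIF4E-1 (the 1L8B crystal-structure protein), 217 aa, canonical
# numbering: the cap-binding aromatics sit at W43/W46/W56/W73/W102/W113/
# W130/W166, with E103, R112, R157 and K162 completing the binding pocket.
.MURINE_EIF4E <- paste0(
  "MATVEPETTPTPNPPTTEEEKTESNQEVANPEHYIKHPLQNRWALWFFKNDKSKTWQANLRLISKFDTVE",
  "DFWALYNHIQLSSNLMPGCDYSLFKDGIEPMWEDEKNKRGGRWLITLNKQQRRSDLDRFWLETLLCLIGE",
  "SFDDYSDDVCGAVVNVRAKGDKIAIWTTECENREAVTHIGRVYKERLGLPPKIVIGYQSHADTATKSGST",
  "TKNRFVV")

#' Amino-acid alphabet (PAML ordering)
#'
#' The twenty standard amino acids in the ordering used by empirical
#' substitution models (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Murine eIF4E reference sequence
#'
#' The full-length murine eIF4E-1 protein used as the numbering reference for
#' the whole package: every anchored alignment reports residue positions on
#' this sequence's 1-based coordinates.
#'
#' @param core If `TRUE`, return only the core cap-binding domain (positions
#'   38-176, i.e. five residues upstream of W43 through ten residues
#'   downstream of W166); the record then carries an `offset` attribute with
#'   the 1-based position of its first residue.
#' @return A [seq_record()] with group `"reference"`.
#' @examples
#' ref <- eif4e_reference()
#' substr(ref$residues, 56, 56)  # "W", the cap-stacking tryptophan
#' @export
eif4e_reference <- function(core = FALSE) {
  res <- .MURINE_EIF4E
  off <- 1L
  if (core) {
    w <- reference_anchors()
    res <- substr(res, w$core_start, w$core_end)
    off <- w$core_start
  }
  rec <- seq_record(id = "Mmus_eIF4E1", residues = res,
                    species = "Mus musculus", group = "reference")
  attr(rec, "offset") <- off
  rec
}

#' Cap-binding anchor positions on the murine reference
#'
#' Returns the diagnostic murine eIF4E positions used throughout the package:
#' the cap-sandwich tryptophans (W56, W102), the methyl-recognition W166, the
#' charged phosphate-bridge contacts (R112, R157, K162), E103, the eIF4G motif
#' terminus W73, and the aromatics W43/W46/W130. Also returns the core-domain
#' trimming window (five residues upstream of W43 to ten downstream of W166)
#' and the two insertion windows (W73-W102 and W130-W166) where clade-1 family
#' members carry extended sequence.
#'
#' @param upstream,downstream Window margins around W43 and W166 (residues).
#' @return List with `anchors` (named integer vector), `core_start`,
#'   `core_end`, `positions` (integer vector of the core columns) and
#'   `insertion_windows` (list of two integer pairs).
#' @export
reference_anchors <- function(upstream = 5L, downstream = 10L) {
  stopifnot(upstream >= 0, downstream >= 0)
  anchors <- c(W43 = 43L, W46 = 46L, W56 = 56L, W73 = 73L, W102 = 102L,
               E103 = 103L, R112 = 112L, W130 = 130L, R157 = 157L,
               K162 = 162L, W166 = 166L)
  core_start <- anchors[["W43"]] - as.integer(upstream)
  core_end <- anchors[["W166"]] + as.integer(downstream)
  list(anchors = anchors,
       core_start = core_start,
       core_end = core_end,
       positions = seq.int(core_start, core_end),
       insertion_windows = list(c(73L, 102L), c(130L, 166L)))
}

#' BLOSUM62 scoring matrix
#'
#' The BLOSUM62 substitution matrix (from Biostrings), restricted to the 20
#' standard residues plus X. Following the census conventions, X scores 0
#' against every residue so that unknown positions neither reward nor
#' penalise an alignment.
#'
#' @param x_zero If `TRUE` (default) zero the X row/column.
#' @return Integer matrix with dimnames over the alphabet plus `"X"`.
#' @export
blosum62 <- function(x_zero = TRUE) {
  mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment())[1], envir = environment())
  keep <- c(aa_alphabet(), "X")
  mat <- mat[keep, keep]
  if (x_zero) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

.model_tables <- function(name) {
  # Pull the published exchangeabilities / frequencies from phangorn's model
  # tables; getModelAA assigns Q (190 lower-triangle entries, PAML order) and
  # bf (20 frequencies) into the evaluation environment.
  env <- new.env()
  fun <- utils::getFromNamespace("getModelAA", "phangorn")
  eval(as.call(list(fun, name, bf = TRUE, Q = TRUE)), envir = env)
  aa <- aa_alphabet()
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- env$Q
  S <- S + t(S)
  bf <- env$bf
  names(bf) <- aa
  list(S = S, bf = bf / sum(bf))
}

#' Empirical amino-acid substitution model with discrete-gamma rates
#'
#' Builds a reversible amino-acid substitution model from a published
#' exchangeability matrix (LG, WAG or JTT) and a frequency vector, normalised
#' to one expected substitution per site per unit branch length, with
#' discrete-gamma among-site rate variation (mean rate of each
#' equal-probability category).
#'
#' @param name One of `"LG"`, `"WAG"`, `"JTT"`.
#' @param gamma_shape Gamma shape alpha (> 0). `Inf` disables rate variation.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param frequencies Either `"model"` (the matrix's own frequencies, the
#'   choice that gave the better likelihoods in the family survey),
#'   or a numeric vector of 20 frequencies (e.g. empirical alignment
#'   frequencies) in the [aa_alphabet()] order.
#' @return An object of class `substitution_model`: exchangeabilities `S`,
#'   frequencies `pi`, normalised rate matrix `Q`, its eigensystem, the
#'   gamma settings and category rates.
#' @examples
#' m <- substitution_model("LG", gamma_shape = 0.8)
#' rowSums(m$Q)  # ~0: proper rate matrix
#' @export
substitution_model <- function(name = c("LG", "WAG", "JTT"),
                               gamma_shape = 1, n_categories = 4L,
                               frequencies = "model") {
  name <- match.arg(name)
  stopifnot(gamma_shape > 0, n_categories >= 1)
  tab <- .model_tables(name)
  if (identical(frequencies, "model")) {
    pi <- tab$bf
  } else {
    stopifnot(is.numeric(frequencies), length(frequencies) == 20)
    pi <- as.numeric(frequencies)
    names(pi) <- aa_alphabet()
    pi <- pmax(pi, 1e-8)
    pi <- pi / sum(pi)
  }
  if (abs(sum(pi) - 1) > 1e-12) stop("frequencies must sum to 1")
  Q <- tab$S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # mean rate; normalise to 1
  Q <- Q / mu
  dimnames(Q) <- list(aa_alphabet(), aa_alphabet())
  # reversible Q: symmetrise with sqrt(pi) for a stable eigensystem
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = name, S = tab$S, pi = pi, Q = Q,
                 eigen = list(values = eig$values,
                              vectors = eig$vectors, sqrt_pi = sp),
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 rates = discrete_gamma_rates(gamma_shape,
                                              as.integer(n_categories))),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("%s substitution model (+G, alpha = %g, %d categories)\n",
              x$name, x$gamma_shape, x$n_categories))
  cat("category rates:", format(x$rates, digits = 4), "\n")
  invisible(x)
}

#' Discrete-gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretisation for among-site rate
#' variation.
#'
#' @param alpha Shape parameter (> 0); `Inf` gives a single unit rate.
#' @param k Number of categories.
#' @return Numeric vector of length `k` with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || k == 1L) return(rep(1, k))
  stopifnot(alpha > 0, k >= 1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean of each slice via the incomplete-gamma identity
  p <- stats::pgamma(b * alpha, shape = alpha + 1, rate = 1)
  r <- k * diff(p)
  r / mean(r) * 1  # guard tiny numerical drift; mean exactly 1
}

#' Transition probability matrix P(t)
#'
#' Matrix exponential `exp(Qt)` of a [substitution_model()] rate matrix,
#' computed from the model's cached eigensystem.
#'
#' @param model A `substitution_model`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  e <- model$eigen
  P <- (e$vectors %*% (t(e$vectors) * exp(e$values * t)))
  P <- (1 / e$sqrt_pi) * P * rep(e$sqrt_pi, each = 20)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P / rowSums(P)
}
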