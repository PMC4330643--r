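# Synthetic family generator: evolves a protein superfamily down an explicit
# guide tree rooted at the murine eIF4E core, with clade-diagnostic residue
# signatures written at each clade's ancestral node, sub-clade-specific
# divergence levels, optional composition-biased long-branch lineages, and
# known truth labels for every sequence. There is no indel process during
# branch evolution -- insertions enter only through the clade signatures --
# so the murine numbering of every site is known exactly.

#' Clade signature
#'
#' The residue states, insertions and motif written at a clade's ancestral
#' node before descent.
#'
#' @param states Named character vector of forced states, names = murine
#'   positions (e.g. `c("56" = "Y", "112" = "H")`).
#' @param insertions List of `list(window = c(lo, hi), length = n)` specs;
#'   the segment is inserted after the window midpoint.
#' @param motif Optional hexamer written at murine 68-73.
#' @param cterm_ext Length of a C-terminal extension appended beyond the
#'   core (0 = none).
#' @return Object of class `clade_signature`.
#' @export
clade_signature <- function(states = character(0), insertions = list(),
                            motif = NULL, cterm_ext = 0L) {
  stopifnot(all(nchar(states) == 1),
            all(vapply(insertions, function(i) i$length >= 0, TRUE)),
            is.null(motif) || nchar(motif) == 6, cterm_ext >= 0)
  structure(list(states = states, insertions = insertions, motif = motif,
                 cterm_ext = as.integer(cterm_ext)),
            class = "clade_signature")
}

.default_signatures <- function() {
  list(
    # clade 1: Y56, H112, R162, extended segments in both windows, polar
    # eIF4G motif (the 1a/1b TVQeFW type)
    clade_signature(states = c("56" = "Y", "112" = "H", "162" = "R"),
                    insertions = list(list(window = c(73L, 102L), length = 10L),
                                      list(window = c(130L, 166L), length = 8L)),
                    motif = "TVQEFW"),
    # clade 2: Y56, C112, V162, Y73 motif terminus, long C-terminal
    # extension (the 2a-type carboxy extension)
    clade_signature(states = c("56" = "Y", "112" = "C", "162" = "V"),
                    motif = "TVSALY", cterm_ext = 230L),
    # clade 3: canonical cap-binding set W56/R112/K162
    clade_signature(states = c("56" = "W", "112" = "R", "162" = "K"),
                    motif = "SVGSFW"))
}

.CORE_DINO_SPECIES <- c(
  "Akashiwo sanguinea", "Alexandrium tamarense", "Amphidinium carterae",
  "Gyrodinium instriatum", "Karenia brevis", "Karlodinium veneficum",
  "Lingulodinium polyedrum", "Polarella glacialis", "Prorocentrum minimum",
  "Scrippsiella trochoidea", "Symbiodinium sp.")

.HETEROKONT_SPECIES <- c("Ectocarpus siliculosus", "Phytophthora infestans",
                         "Thalassiosira pseudonana", "Albugo laibachii")

.CILIATE_SPECIES <- c("Tetrahymena thermophila", "Paramecium tetraurelia",
                      "Oxytricha trifallax")

#' Simulation configuration
#'
#' Default settings describe a family of three ancestral clades, each split
#' into three core-dinoflagellate sub-clades across eleven species with one
#' to three copies per species, plus heterokont representatives in every
#' clade and composition-biased long-branch ciliate lineages in clade 1.
#' Sub-clade species representation defaults to (11,11,11), (11,11,8) and
#' (11,6,5), so that six of the nine sub-clades carry every species, and
#' divergence scalars increase from sub-clade a to c, mirroring the
#' conservation ranking seen in the family.
#'
#' Within each clade the sub-clades attach along a short spine, separated
#' by outgroup lineages (heterokont lineages in every clade, a syndinean in
#' clade 1, Perkinsus in clade 3), emulating the interleaving of outgroup
#' taxa among sub-clades seen in the family tree; a sub-clade is therefore
#' a maximal monophyletic core-dinoflagellate group in the guide tree.
#'
#' @param seed Integer seed driving all randomness.
#' @param species Core-dinoflagellate species (default the eleven bloom
#'   formers of the survey).
#' @param model_name Substitution model for branch evolution (default LG).
#' @param clade_stem,subclade_stem,hk_stem,hk_tip,spine,copy_branch Branch
#'   lengths (expected substitutions/site) for the guide tree.
#' @param divergence Per-clade list of per-sub-clade species branch
#'   lengths; larger = less conserved.
#' @param copies Per-clade list of per-sub-clade `c(min, max)` copy-number
#'   ranges per species.
#' @param presence Per-clade integer vectors: number of species represented
#'   in each sub-clade.
#' @param signatures Per-clade [clade_signature()]s.
#' @param bias `list(n, weight, target, stem, tip)`: number of biased
#'   ciliate tips placed in clade 1, per-site resampling weight, target
#'   frequency vector (20, alphabet order), and their branch lengths.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       species = .CORE_DINO_SPECIES,
                       model_name = "LG",
                       clade_stem = 0.40, subclade_stem = 0.22,
                       hk_stem = 0.15, hk_tip = 0.10,
                       spine = 0.12,
                       copy_branch = 0.02,
                       divergence = rep(list(c(0.03, 0.08, 0.15)), 3),
                       copies = rep(list(list(c(1L, 3L), c(1L, 1L),
                                              c(1L, 1L))), 3),
                       presence = list(c(11L, 11L, 11L),
                                       c(11L, 11L, 8L),
                                       c(11L, 6L, 5L)),
                       signatures = .default_signatures(),
                       bias = list(n = 3L, weight = 0.50,
                                   target = NULL, stem = 0.35, tip = 0.15)) {
  n_clades <- length(signatures)
  stopifnot(length(divergence) == n_clades, length(copies) == n_clades,
            length(presence) == n_clades,
            all(unlist(presence) <= length(species)),
            all(vapply(unlist(copies, recursive = FALSE),
                       function(cc) cc[1] <= cc[2] && cc[1] >= 0, TRUE)),
            bias$weight >= 0, bias$weight <= 1)
  if (is.null(bias$target)) {
    # AT-rich-proteome style skew: over-represent F/I/K/N, deplete A/G/R
    target <- rep(1 / 20, 20)
    names(target) <- aa_alphabet()
    target[c("F", "I", "K", "N")] <- target[c("F", "I", "K", "N")] + 0.10
    target[c("A", "G", "R", "P")] <- pmax(target[c("A", "G", "R", "P")] - 0.03,
                                          0.005)
    bias$target <- target / sum(target)
  }
  structure(list(seed = as.integer(seed), species = species,
                 model_name = model_name, clade_stem = clade_stem,
                 subclade_stem = subclade_stem, hk_stem = hk_stem,
                 hk_tip = hk_tip, spine = spine, copy_branch = copy_branch,
                 divergence = divergence, copies = copies,
                 presence = presence, signatures = signatures,
                 bias = bias, n_clades = n_clades),
            class = "sim_config")
}

#' Evolve a sequence along a branch
#'
#' i.i.d. per-site substitution with the model's transition probabilities
#' P(t); sequence length is preserved (no indels). Uses R's global RNG.
#'
#' @param parent Residue string.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @param model A [substitution_model()].
#' @return Residue string of the same length.
#' @export
evolve_sequence <- function(parent, t, model = substitution_model("LG")) {
  stopifnot(t >= 0)
  if (t == 0) return(parent)
  res <- strsplit(parent, "")[[1]]
  aa <- aa_alphabet()
  idx <- match(res, aa)
  P <- transition_prob(model, t)
  out <- res
  for (a in unique(idx[!is.na(idx)])) {
    sites <- which(idx == a)
    out[sites] <- sample(aa, length(sites), replace = TRUE, prob = P[a, ])
  }
  paste(out, collapse = "")
}

# internal sequence-with-numbering representation
.sim_seq <- function(residues, pos) list(res = residues, pos = pos)

.evolve_node <- function(node, t, model) {
  .sim_seq(evolve_sequence(node$res, t, model), node$pos)
}

#' Write a clade signature onto a numbered sequence
#'
#' Forces the signature states at their murine positions, writes the eIF4G
#' motif hexamer at 68-73, inserts the signature segments after each
#' insertion window's midpoint, and appends any C-terminal extension.
#' Idempotent: applying a signature twice changes nothing further.
#'
#' @param seq Residue string.
#' @param pos Integer vector of murine positions per residue (NA =
#'   insertion), same length as the sequence.
#' @param sig A [clade_signature()].
#' @param model Model supplying residue frequencies for inserted segments.
#' @return List with updated `res` and `pos`.
#' @export
apply_clade_signature <- function(seq, pos, sig,
                                  model = substitution_model("LG")) {
  stopifnot(inherits(sig, "clade_signature"),
            nchar(seq) == length(pos))
  res <- strsplit(seq, "")[[1]]
  aa <- aa_alphabet()
  put <- function(p, ch) {
    i <- match(p, pos)
    if (is.na(i)) stop("unmapped anchor position ", p)
    res[i] <<- ch
  }
  for (k in seq_along(sig$states))
    put(as.integer(names(sig$states)[k]), sig$states[[k]])
  if (!is.null(sig$motif)) {
    chars <- strsplit(sig$motif, "")[[1]]
    for (k in 1:6) put(67L + k, chars[k])
  }
  for (ins in sig$insertions) {
    mp <- as.integer(floor(mean(ins$window)))
    i <- match(mp, pos)
    if (is.na(i)) stop("unmapped insertion anchor ", mp)
    # idempotence: skip when the segment is already present
    j <- i + 1L
    run <- 0L
    while (j <= length(pos) && is.na(pos[j])) { run <- run + 1L; j <- j + 1L }
    if (run >= ins$length) next
    need <- ins$length - run
    seg <- sample(aa, need, replace = TRUE, prob = model$pi)
    res <- append(res, seg, after = i + run)
    pos <- append(pos, rep(NA_integer_, need), after = i + run)
  }
  if (sig$cterm_ext > 0) {
    last_mapped <- max(which(!is.na(pos)))
    run <- length(pos) - last_mapped
    if (run < sig$cterm_ext) {
      need <- sig$cterm_ext - run
      seg <- sample(aa, need, replace = TRUE, prob = model$pi)
      res <- c(res, seg)
      pos <- c(pos, rep(NA_integer_, need))
    }
  }
  .sim_seq(paste(res, collapse = ""), pos)
}

.bias_sequence <- function(resstr, weight, target) {
  res <- strsplit(resstr, "")[[1]]
  hit <- stats::runif(length(res)) < weight
  if (any(hit))
    res[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE,
                       prob = target)
  paste(res, collapse = "")
}

.species_code <- function(s) {
  parts <- strsplit(s, "\\s+")[[1]]
  paste0(substr(parts[1], 1, 1),
         substr(parts[length(parts)], 1, 3))
}

#' Simulate a synthetic eIF4E-like family
#'
#' Evolves the murine eIF4E core down the configured guide tree: each clade
#' ancestor receives its [clade_signature()] before descent; each sub-clade
#' diverges at its own level; species carry one or more copies; designated
#' ciliate lineages are composition-biased by per-site resampling toward a
#' target frequency vector. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_family`: `records` (a [seq_set()]),
#'   `truth` (data.frame id, clade, subclade, species, group), `tree` (the
#'   true guide `phylo`), `seeds` (clade-ancestor records usable as census
#'   queries), and `config`.
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  model <- substitution_model(cfg$model_name)
  withr_seed(cfg$seed, {
    anch <- reference_anchors()
    ref <- eif4e_reference(core = TRUE)
    root <- .sim_seq(ref$residues, anch$positions)
    records <- list(); truth <- list(); seeds <- list()
    newick_clades <- character(cfg$n_clades)
    tip <- function(id, node, species, group, clade, subclade,
                    bias = NULL) {
      res <- node$res
      if (!is.null(bias)) res <- .bias_sequence(res, bias$weight, bias$target)
      records[[id]] <<- seq_record(id, res, species, group)
      truth[[id]] <<- data.frame(id = id, clade = clade, subclade = subclade,
                                 species = species, group = group)
    }
    for (c_i in seq_len(cfg$n_clades)) {
      clade_name <- sprintf("eIF4E-%d", c_i)
      anc <- .evolve_node(root, cfg$clade_stem, model)
      anc <- apply_clade_signature(anc$res, anc$pos, cfg$signatures[[c_i]],
                                   model)
      seeds[[c_i]] <- seq_record(sprintf("seed_clade%d", c_i), anc$res,
                                 species = "synthetic ancestor",
                                 group = "other")
      # a core-dinoflagellate sub-clade subtree: "(...)name:stem"
      sub_str <- function(s_i, node) {
        sub_name <- sprintf("%d%s", c_i, letters[s_i])
        sc_anc <- .evolve_node(node, cfg$subclade_stem, model)
        pres <- cfg$presence[[c_i]][s_i]
        sp_here <- if (pres >= length(cfg$species)) cfg$species else
          sort(sample(cfg$species, pres))
        scalar <- cfg$divergence[[c_i]][s_i]
        cc <- cfg$copies[[c_i]][[s_i]]
        sp_parts <- character(0)
        for (sp in sp_here) {
          sp_node <- .evolve_node(sc_anc, scalar, model)
          ncopy <- if (cc[1] == cc[2]) cc[1] else
            sample(seq.int(cc[1], cc[2]), 1)
          if (ncopy == 0) next
          ids <- character(ncopy)
          for (k in seq_len(ncopy)) {
            cp <- .evolve_node(sp_node, cfg$copy_branch, model)
            id <- sprintf("d%s_%s_%d", sub_name, .species_code(sp), k)
            tip(id, cp, sp, "core_dino", clade_name, sub_name)
            ids[k] <- id
          }
          sp_parts <- c(sp_parts, if (ncopy == 1)
            sprintf("%s:%g", ids[1], scalar + cfg$copy_branch) else
              sprintf("(%s):%g",
                      paste(sprintf("%s:%g", ids, cfg$copy_branch),
                            collapse = ","), scalar))
        }
        sprintf("(%s):%g", paste(sp_parts, collapse = ","),
                cfg$subclade_stem)
      }
      # separator lineages interleaved between sub-clades: every clade has
      # heterokont representation; clade 1 also carries a syndinean and the
      # biased ciliates, clade 3 a Perkinsus lineage
      # a two-tip outgroup lineage (heterokont pair, Amoebophrya strains,
      # Perkinsus copies): paired tips stabilise the lineage's placement
      og_pair_str <- function(species_names, group, prefix, node) {
        og_anc <- .evolve_node(node, cfg$hk_stem, model)
        ids <- character(length(species_names))
        for (h in seq_along(species_names)) {
          node <- .evolve_node(og_anc, cfg$hk_tip, model)
          id <- sprintf("%s%d_%s_%d", prefix, c_i,
                        .species_code(species_names[h]), h)
          tip(id, node, species_names[h], group, clade_name, NA_character_)
          ids[h] <- id
        }
        sprintf("(%s):%g",
                paste(sprintf("%s:%g", ids, cfg$hk_tip), collapse = ","),
                cfg$hk_stem)
      }
      hk_pair_str <- function(which_sp, node) {
        sp <- .HETEROKONT_SPECIES[((which_sp - 1) + 0:1) %%
                                    length(.HETEROKONT_SPECIES) + 1]
        og_pair_str(sp, "heterokont", "hk", node)
      }
      cil_str <- function(node) {
        cil_anc <- .evolve_node(node, cfg$bias$stem, model)
        cil_ids <- character(cfg$bias$n)
        for (h in seq_len(cfg$bias$n)) {
          node <- .evolve_node(cil_anc, cfg$bias$tip, model)
          spc <- .CILIATE_SPECIES[(h - 1) %% length(.CILIATE_SPECIES) + 1]
          id <- sprintf("cil%d_%s", h, .species_code(spc))
          tip(id, node, spc, "ciliate", clade_name, NA_character_,
              bias = cfg$bias)
          cil_ids[h] <- id
        }
        sprintf("(%s):%g",
                paste(sprintf("%s:%g", cil_ids, cfg$bias$tip),
                      collapse = ","), cfg$bias$stem)
      }
      sep_str <- function(k, node) {
        if (c_i == 1L && k == 1L)
          return(og_pair_str(rep("Amoebophrya sp.", 2), "syndinean", "syn",
                             node))
        if (c_i == 1L && k == 2L) {
          bundle <- .evolve_node(node, cfg$spine, model)
          hk <- hk_pair_str(1, bundle)
          return(if (cfg$bias$n > 0)
            sprintf("(%s,%s):%g", hk, cil_str(bundle), cfg$spine) else
              hk_pair_str(1, node))
        }
        if (c_i == 3L && k == 2L)
          return(og_pair_str(rep("Perkinsus marinus", 2), "perkinsus", "pk",
                             node))
        hk_pair_str(c_i + k, node)
      }
      # ladder: sub_1, then (sep_1, (sub_2, (sep_2, sub_3))); separators
      # evolve from the spine node they attach to
      ladder <- function(s_i, node) {
        if (s_i == length(cfg$divergence[[c_i]]))
          return(sub_str(s_i, node))
        sp_node <- .evolve_node(node, cfg$spine, model)
        inner <- paste(sep_str(s_i, sp_node), ladder(s_i + 1, sp_node),
                       sep = ",")
        paste(sub_str(s_i, node),
              sprintf("(%s):%g", inner, cfg$spine), sep = ",")
      }
      newick_clades[c_i] <- sprintf("(%s):%g", ladder(1L, anc),
                                    cfg$clade_stem)
    }
    nwk <- sprintf("(%s);", paste(newick_clades, collapse = ","))
    tree <- read_newick(nwk)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(records = seq_set(unname(records)),
                   truth = truth, tree = tree,
                   seeds = seq_set(seeds), config = cfg),
              class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("synthetic eIF4E family: %d sequences, %d clades, %d sub-clades, seed %d\n",
              nrow(x$truth), length(unique(x$truth$clade)),
              length(unique(stats::na.omit(x$truth$subclade))),
              x$config$seed))
  print(table(x$truth$group))
  invisible(x)
}

#' Sub-clade recovery accuracy against simulation truth
#'
#' Matches recovered sub-clades to generating sub-clades greedily by
#' overlap (largest first) and reports the percentage of truth-labelled
#' core-dinoflagellate sequences assigned to the sub-clade matched with
#' their generating one. Lettering conventions on either side do not
#' matter; only the groupings do.
#'
#' @param partition A `clade_partition` with sub-clades.
#' @param truth Truth data.frame from [simulate_family()].
#' @return Percentage in [0, 100].
#' @export
subclade_accuracy <- function(partition, truth) {
  stopifnot(inherits(partition, "clade_partition"))
  truth <- truth[!is.na(truth$subclade), , drop = FALSE]
  found <- lapply(partition$subclades, `[[`, "leaves")
  names(found) <- vapply(partition$subclades, `[[`, "", "name")
  true_groups <- split(truth$id, truth$subclade)
  pairs <- expand.grid(f = names(found), t = names(true_groups),
                       stringsAsFactors = FALSE)
  if (!nrow(pairs) || !nrow(truth)) return(0)
  pairs$overlap <- mapply(function(f, t)
    length(intersect(found[[f]], true_groups[[t]])),
    pairs$f, pairs$t)
  pairs <- pairs[order(-pairs$overlap), ]
  used_f <- character(0); used_t <- character(0); correct <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (pairs$overlap[i] == 0) break
    if (pairs$f[i] %in% used_f || pairs$t[i] %in% used_t) next
    used_f <- c(used_f, pairs$f[i]); used_t <- c(used_t, pairs$t[i])
    correct <- correct + pairs$overlap[i]
  }
  100 * correct / nrow(truth)
}
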