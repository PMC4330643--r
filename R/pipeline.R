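# Pipeline orchestration: a plain-text key=value configuration drives the
# stages census -> align -> annotate -> tree -> clades -> stats, writing TSV
# and FASTA artifacts into an output directory with a single log and a
# metadata record of every threshold. Stages can be resumed from cached
# outputs.

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values keep their
#' string form (callers coerce). Later keys override earlier ones.
#'
#' @param path Config file.
#' @return Named list of strings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  out <- list()
  for (line in readLines(path, warn = FALSE)) {
    line <- sub("#.*$", "", line)
    if (!grepl("=", line, fixed = TRUE)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (nzchar(key))
      out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

.cfg_num <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}
.cfg_str <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}
.cfg_flag <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else
    tolower(cfg[[key]]) %in% c("1", "true", "yes")
}

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the family-survey pipeline
#'
#' Executes the stages census, align, annotate, tree, clades and stats in
#' order. Inputs come either from FASTA files named in the config
#' (`queries`, `db` as comma-separated paths) or from the synthetic family
#' generator (`source = simulate`). With `resume = true`, a stage whose
#' outputs already exist is skipped.
#'
#' Config keys (defaults in parentheses): `source` (simulate), `out_dir`
#' (required), `seed` (42), `evalue` (1e-10), `min_len` (130), `method`
#' (kimura), `bootstrap` (100), `model` (LG), `alpha` (0.05), `resume`
#' (false), `census` (true; `false` starts from sequences named by `seqs`),
#' `sim_species` (number of core-dinoflagellate species for the simulated
#' source; fewer species give a reduced smoke-test family).
#'
#' @param config Path to a config file, or a named list as from
#'   [read_config()].
#' @return Object of class `capclade_run`: output paths plus run metadata
#'   (seed and all thresholds).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- .cfg_str(cfg, "out_dir", NULL)
  if (is.null(out_dir)) stop("config must name out_dir")
  source <- .cfg_str(cfg, "source", "simulate")
  if (source == "files") {
    for (key in c("queries")) {
      paths <- strsplit(.cfg_str(cfg, key, ""), ",")[[1]]
      bad <- paths[!file.exists(trimws(paths))]
      if (!nzchar(.cfg_str(cfg, key, "")) || length(bad))
        stop("missing input for '", key, "': ",
             paste(bad, collapse = ", "))
    }
    dbs <- trimws(strsplit(.cfg_str(cfg, "db", ""), ",")[[1]])
    if (!length(dbs) || any(!file.exists(dbs)))
      stop("missing input for 'db'")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfg_num(cfg, "seed", 42))
  resume <- .cfg_flag(cfg, "resume", FALSE)
  params <- search_params(evalue_cutoff = .cfg_num(cfg, "evalue", 1e-10),
                          min_aligned_length = .cfg_num(cfg, "min_len", 130))
  method <- .cfg_str(cfg, "method", "kimura")
  B <- as.integer(.cfg_num(cfg, "bootstrap", 100))
  alpha <- .cfg_num(cfg, "alpha", 0.05)
  log_con <- file(file.path(out_dir, "run.log"), "a")
  on.exit(close(log_con))
  paths <- list(census = file.path(out_dir, "census.tsv"),
                aln = file.path(out_dir, "core.aln.fasta"),
                map = file.path(out_dir, "numbering.tsv"),
                residues = file.path(out_dir, "residues.tsv"),
                tree = file.path(out_dir, "tree.nwk"),
                clades = file.path(out_dir, "clades.tsv"),
                rep = file.path(out_dir, "rep.tsv"),
                composition = file.path(out_dir, "composition.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  .log_line(log_con,
            "pipeline start: source=%s seed=%d evalue=%g min_len=%d method=%s B=%d alpha=%g",
            source, seed, params$evalue_cutoff, params$min_aligned_length,
            method, B, alpha)

  # inputs
  if (source == "simulate") {
    simcfg <- sim_config(seed = seed)
    k <- as.integer(.cfg_num(cfg, "sim_species", length(simcfg$species)))
    if (k < length(simcfg$species))
      simcfg <- sim_config(seed = seed, species = simcfg$species[seq_len(k)],
                           presence = lapply(simcfg$presence,
                                             function(p) pmin(p, k)))
    fam <- simulate_family(simcfg)
    db <- fam$records
    queries <- fam$seeds
    write_tsv_table(fam$truth, paths$truth)
  } else {
    db <- list()
    for (p in dbs) db[[length(db) + 1L]] <- read_fasta(p)
    queries <- read_fasta(trimws(.cfg_str(cfg, "queries", "")))
    fam <- NULL
  }

  # census
  if (.cfg_flag(cfg, "census", TRUE)) {
    if (resume && file.exists(paths$census)) {
      .log_line(log_con, "census: cached")
      census <- structure(read_tsv_table(paths$census),
                          class = c("census_table", "data.frame"))
    } else {
      census <- iterative_census(queries, db, params)
      write_tsv_table(as.data.frame(census), paths$census)
      .log_line(log_con, "census: %d members in %d rounds", nrow(census),
                attr(census, "n_rounds"))
    }
    pool <- list()
    dbl <- if (inherits(db, "seq_set")) list(db) else db
    for (d in dbl) for (r in d) if (is.null(pool[[r$id]])) pool[[r$id]] <- r
    members <- seq_set(unname(pool[census$member_id]))
  } else {
    census <- NULL
    members <- read_fasta(.cfg_str(cfg, "seqs", ""))
  }

  # align + trim + stack
  alns <- lapply(members, align_to_reference, params = params)
  trimmed <- list()
  for (a in alns) {
    trimmed[[length(trimmed) + 1L]] <-
      tryCatch(trim_core(a), error = function(e) NULL)
  }
  kept <- !vapply(trimmed, is.null, TRUE)
  m <- stack_alignment(trimmed[kept])
  write_alignment_fasta(m, paths$aln)
  write_tsv_table(do.call(rbind, lapply(trimmed[kept], numbering_table)),
                  paths$map)
  .log_line(log_con, "align: %d/%d sequences anchored to the core window",
            sum(kept), length(alns))

  # annotate
  ann <- annotate_alignment(m)
  write_tsv_table(ann, paths$residues)
  .log_line(log_con, "annotate: %d sequences, %d classified",
            nrow(ann), sum(ann$label != "unclassified"))

  # tree
  ts <- bootstrap_support(m, B = B, seed = seed, method = method)
  write_newick(ts, paths$tree)
  .log_line(log_con, "tree: %d tips, %d bootstrap replicates",
            length(ts$tip.label), B)

  # clades
  groups <- stats::setNames(
    vapply(members, `[[`, "", "group"),
    vapply(members, `[[`, "", "id"))[ts$tip.label]
  species <- stats::setNames(
    vapply(members, `[[`, "", "species"),
    vapply(members, `[[`, "", "id"))[ts$tip.label]
  part <- partition_major_clades(ts, groups)
  part <- find_subclades(part, species)
  sc_rows <- lapply(part$subclades, function(sc)
    data.frame(subclade = sc$name, major = sc$major,
               n_members = length(sc$leaves), n_species = sc$n_species,
               members = paste(sc$leaves, collapse = ",")))
  write_tsv_table(do.call(rbind, sc_rows) %||%
                    data.frame(subclade = character(0)), paths$clades)
  rep_tab <- NULL
  if (!is.null(census) && length(part$subclades)) {
    rep_tab <- representation_table(part, census)
    rep_df <- data.frame(subclade = rownames(rep_tab$counts),
                         rep_tab$counts, check.names = FALSE)
    write_tsv_table(rep_df, paths$rep)
  }
  .log_line(log_con, "clades: %d major, %d sub-clades",
            length(part$clades), length(part$subclades))

  # stats
  comp <- composition_chi2(m, alpha = alpha)
  write_tsv_table(as.data.frame(comp), paths$composition)
  for (sc in part$subclades) {
    lm <- logo_matrix(m$matrix[intersect(sc$leaves, rownames(m$matrix)), ,
                               drop = FALSE])
    write_tsv_table(as.data.frame(lm),
                    file.path(out_dir, sprintf("logo_%s.tsv", sc$name)))
  }
  .log_line(log_con, "stats: %d/%d rows composition-flagged at alpha=%g",
            sum(comp$flagged), nrow(comp), alpha)

  structure(list(paths = paths, out_dir = out_dir,
                 census = census, alignment = m, annotation = ann,
                 tree = ts, partition = part, representation = rep_tab,
                 composition = comp, truth = if (!is.null(fam)) fam$truth,
                 metadata = list(seed = seed, source = source,
                                 evalue_cutoff = params$evalue_cutoff,
                                 min_aligned_length = params$min_aligned_length,
                                 method = method, bootstrap = B,
                                 alpha = alpha,
                                 version = as.character(
                                   utils::packageVersion("capclade")))),
            class = "capclade_run")
}

#' @export
print.capclade_run <- function(x, ...) {
  cat(sprintf("capclade run (seed %d, %s source)\n", x$metadata$seed,
              x$metadata$source))
  if (!is.null(x$census))
    cat(sprintf("  census: %d members\n", nrow(x$census)))
  cat(sprintf("  alignment: %d rows x %d columns\n",
              length(x$alignment$ids), length(x$alignment$positions)))
  cat(sprintf("  partition: %d major clades, %d sub-clades\n",
              length(x$partition$clades), length(x$partition$subclades)))
  cat("  outputs in ", x$out_dir, "\n")
  invisible(x)
}

#' Census summary table
#'
#' Per-species member totals with the core-dinoflagellate range and mean,
#' and (when a representation table is supplied) per-sub-clade counts: the
#' headline numbers of a family survey.
#'
#' @param census A `census_table`.
#' @param rep Optional `rep_table`.
#' @return Object of class `census_summary`: `per_species` (data.frame),
#'   `core_range` (min, max), `core_mean`, `total`, optional
#'   `per_subclade`.
#' @export
census_summary <- function(census, rep = NULL) {
  if (!nrow(census)) {
    return(structure(list(per_species = data.frame(species = character(0),
                                                   group = character(0),
                                                   n = integer(0)),
                          core_range = c(NA_integer_, NA_integer_),
                          core_mean = NA_real_, total = 0L,
                          per_subclade = NULL),
                     class = "census_summary"))
  }
  per <- stats::aggregate(list(n = census$member_id),
                          by = list(species = census$species,
                                    group = census$group),
                          FUN = length)
  core <- per$n[per$group == "core_dino"]
  per_subclade <- if (!is.null(rep))
    data.frame(subclade = rownames(rep$counts),
               n_members = rowSums(rep$counts),
               n_species = rep$n_species, full = rep$full)
  structure(list(per_species = per[order(-per$n), ],
                 core_range = if (length(core)) range(core) else
                   c(NA_integer_, NA_integer_),
                 core_mean = if (length(core)) mean(core) else NA_real_,
                 total = nrow(census),
                 per_subclade = per_subclade),
            class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf("census: %d members total\n", x$total))
  if (!is.na(x$core_mean))
    cat(sprintf("core dinoflagellates: %d-%d per species (mean %.1f)\n",
                x$core_range[1], x$core_range[2], x$core_mean))
  print(utils::head(x$per_species, 15), row.names = FALSE)
  if (!is.null(x$per_subclade)) {
    cat("per sub-clade:\n")
    print(x$per_subclade, row.names = FALSE)
  }
  invisible(x)
}
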