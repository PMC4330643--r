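# Sequence and tree I/O: FASTA records with species/group metadata, Newick
# trees with support labels, NEXUS (matrix + trees blocks, TreeBase dialect)
# and TSV report tables. All file coordinates are 1-based; internal interval
# arithmetic is 0-based half-open and confined to this file.

.GROUPS <- c("core_dino", "syndinean", "perkinsus", "apicomplexan",
             "ciliate", "heterokont", "reference", "other")

#' Protein sequence record
#'
#' A single ungapped protein sequence with census metadata. Residues are
#' uppercased; a terminal stop `*` is stripped; any other character outside
#' the 20-letter alphabet plus X is an error.
#'
#' @param id Non-empty unique identifier.
#' @param residues Amino-acid string.
#' @param species Species name (free text).
#' @param group One of the taxon groups: core_dino, syndinean, perkinsus,
#'   apicomplexan, ciliate, heterokont, reference, other.
#' @return Object of class `seq_record` (a named list).
#' @export
seq_record <- function(id, residues, species = "", group = "other") {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("sequence id must be a non-empty string")
  group <- match.arg(group, .GROUPS)
  residues <- toupper(residues)
  residues <- sub("\\*$", "", residues)
  bad <- gsub(sprintf("[%sX]", paste(aa_alphabet(), collapse = "")), "",
              residues)
  if (nzchar(bad))
    stop(sprintf("record '%s' contains non-amino-acid characters: %s",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = " ")))
  structure(list(id = id, species = species, group = group,
                 residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<%s> %s [%s] %d aa\n", x$id, x$species, x$group,
              nchar(x$residues)))
  invisible(x)
}

#' Collection of sequence records
#'
#' @param records List of [seq_record()] objects; ids must be unique.
#' @return Object of class `seq_set` (a list keyed by id).
#' @export
seq_set <- function(records = list()) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id: %s",
                 ids[duplicated(ids)][1]))
  names(records) <- ids
  structure(records, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d sequences\n", length(x)))
  if (length(x)) {
    tab <- table(vapply(x, `[[`, "", "group"))
    cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @method as.data.frame seq_set
#' @export
as.data.frame.seq_set <- function(x, ...) {
  data.frame(id = vapply(x, `[[`, "", "id"),
             species = vapply(x, `[[`, "", "species"),
             group = vapply(x, `[[`, "", "group"),
             length = vapply(x, function(r) nchar(r$residues), 0L),
             row.names = NULL)
}

#' Read protein FASTA
#'
#' Reads a text FASTA file into a [seq_set()]. Headers follow the
#' `id|species|group` convention; missing fields default to empty species and
#' group `"other"`. A sidecar TSV (columns `id`, `species`, `group`) may be
#' supplied and overrides header metadata.
#'
#' @param path FASTA file.
#' @param sidecar Optional TSV path mapping id to species/group.
#' @return A `seq_set`.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">s1|SpA|core_dino", "MKW"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readBStringSet(path)
  headers <- names(aas)
  if (is.null(headers)) headers <- character(0)
  recs <- vector("list", length(aas))
  ids <- character(length(aas))
  for (i in seq_along(aas)) {
    hdr <- trimws(headers[i])
    fields <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(fields) == 1) {
      # plain header: id is the first whitespace-delimited token
      fields[1] <- sub("\\s.*$", "", fields[1])
    } else {
      fields <- trimws(fields)
      # species may contain spaces; the group field may not
      fields[length(fields)] <- sub("\\s.*$", "", fields[length(fields)])
    }
    id <- fields[1]
    species <- if (length(fields) >= 2) fields[2] else ""
    group <- if (length(fields) >= 3 && fields[3] %in% .GROUPS)
      fields[3] else "other"
    recs[[i]] <- seq_record(id, as.character(aas[[i]]), species, group)
    ids[i] <- id
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id in %s: %s", path,
                 ids[duplicated(ids)][1]))
  out <- seq_set(recs)
  if (!is.null(sidecar)) {
    meta <- read_tsv_table(sidecar)
    need <- c("id", "species", "group")
    if (!all(need %in% names(meta)))
      stop("sidecar must have columns id, species, group")
    for (j in seq_len(nrow(meta))) {
      id <- meta$id[j]
      if (!is.null(out[[id]])) {
        out[[id]]$species <- meta$species[j]
        if (meta$group[j] %in% .GROUPS) out[[id]]$group <- meta$group[j]
      }
    }
  }
  out
}

#' Write protein FASTA
#'
#' @param x A `seq_set` or list of `seq_record`s.
#' @param path Output file.
#' @param width Line-wrap width (default 70).
#' @param metadata Include `|species|group` in headers (default TRUE).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L, metadata = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in x) {
    hdr <- if (metadata && (nzchar(r$species) || r$group != "other"))
      sprintf(">%s|%s|%s", r$id, r$species, r$group) else paste0(">", r$id)
    writeLines(hdr, con)
    n <- nchar(r$residues)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Parses a Newick string (or file containing one) into an `ape::phylo`
#' tree. Missing branch lengths default to 0; internal node labels are kept
#' as bootstrap-support annotations (0-100) in `node.label`.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Treat `text` as a path.
#' @return A `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1)90:0.5,C:2);")
#' tr$node.label
#' @export
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("newick parse error: unbalanced ')' at position %d", i))
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of input", depth))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (any(tr$edge.length < 0)) stop("negative branch length in input tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' Write a Newick tree
#'
#' Internal node labels (bootstrap supports) are emitted as Newick internal
#' labels, matching the annotation style used for the family phylogeny.
#'
#' @param tree `phylo` object.
#' @param file Optional output path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

.strip_nexus_comments <- function(s) {
  while (grepl("\\[", s)) {
    s2 <- sub("\\[[^][]*\\]", " ", s)
    if (identical(s2, s)) stop("NEXUS parse error: unclosed '[' comment")
    s <- s2
  }
  s
}

#' Read a NEXUS file
#'
#' Minimal, tolerant NEXUS reader for the dialect used by tree repositories:
#' DATA/CHARACTERS blocks (interleaved or not, optionally quoted taxon
#' labels) and TREES blocks with TRANSLATE tables. Square-bracket comments
#' are ignored anywhere.
#'
#' @param path NEXUS file.
#' @param require `"any"` (default), `"alignment"` or `"trees"`: error if the
#'   named block is absent.
#' @return List with `alignment` (named character vector of gapped rows, or
#'   `NULL`) and `trees` (list of `phylo`).
#' @export
read_nexus <- function(path, require = c("any", "alignment", "trees")) {
  require <- match.arg(require)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#NEXUS", raw, ignore.case = TRUE))
    stop("NEXUS parse error: missing #NEXUS header")
  txt <- .strip_nexus_comments(raw)
  # block extraction
  starts <- gregexpr("(?i)begin\\s+(\\w+)\\s*;", txt, perl = TRUE)[[1]]
  blocks <- list()
  if (starts[1] != -1) {
    lens <- attr(starts, "match.length")
    for (i in seq_along(starts)) {
      head <- substr(txt, starts[i], starts[i] + lens[i] - 1)
      name <- tolower(gsub("(?i)begin\\s+|\\s*;", "", head, perl = TRUE))
      body_start <- starts[i] + lens[i]
      rest <- substr(txt, body_start, nchar(txt))
      endm <- regexpr("(?i)\\bend\\s*;", rest, perl = TRUE)
      if (endm == -1)
        stop(sprintf("NEXUS parse error: block '%s' not terminated (truncated file?)",
                     name))
      blocks[[length(blocks) + 1L]] <-
        list(name = name, body = substr(rest, 1, endm - 1))
    }
  }
  bnames <- vapply(blocks, `[[`, "", "name")
  alignment <- NULL
  trees <- list()
  for (b in blocks) {
    if (b$name %in% c("data", "characters"))
      alignment <- .parse_nexus_matrix(b$body)
    if (b$name == "trees")
      trees <- .parse_nexus_trees(b$body)
  }
  if (require == "alignment" && is.null(alignment))
    stop("NEXUS file has no DATA/CHARACTERS block")
  if (require == "trees" && !length(trees))
    stop("NEXUS file has no TREES block")
  list(alignment = alignment, trees = trees)
}

.parse_nexus_matrix <- function(body) {
  dim_m <- regexpr("(?i)dimensions[^;]*;", body, perl = TRUE)
  ntax <- nchar_exp <- NA_integer_
  if (dim_m != -1) {
    dims <- substr(body, dim_m, dim_m + attr(dim_m, "match.length") - 1)
    g <- function(key) {
      m <- regexpr(sprintf("(?i)%s\\s*=\\s*(\\d+)", key), dims, perl = TRUE)
      if (m == -1) return(NA_integer_)
      as.integer(gsub("\\D", "", regmatches(dims, m)))
    }
    ntax <- g("ntax"); nchar_exp <- g("nchar")
  }
  mat_m <- regexpr("(?i)matrix\\b", body, perl = TRUE)
  if (mat_m == -1) stop("NEXUS parse error: DATA block without MATRIX")
  mtxt <- substr(body, mat_m + attr(mat_m, "match.length"), nchar(body))
  semi <- regexpr(";", mtxt, fixed = TRUE)
  if (semi == -1)
    stop("NEXUS parse error: MATRIX not terminated (truncated file?)")
  mtxt <- substr(mtxt, 1, semi - 1)
  rows <- list()
  for (line in strsplit(mtxt, "\n")[[1]]) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^['\"]", line)) {
      q <- substr(line, 1, 1)
      close_q <- regexpr(q, substr(line, 2, nchar(line)), fixed = TRUE)
      if (close_q == -1) stop("NEXUS parse error: unterminated quoted label")
      name <- substr(line, 2, close_q)
      seqs <- substr(line, close_q + 2, nchar(line))
    } else {
      name <- sub("\\s.*$", "", line)
      seqs <- sub("^\\S+", "", line)
    }
    seqs <- toupper(gsub("\\s", "", seqs))
    if (!nzchar(seqs)) next
    rows[[name]] <- paste0(if (is.null(rows[[name]])) "" else rows[[name]],
                           seqs)
  }
  if (!length(rows)) stop("NEXUS parse error: empty MATRIX")
  out <- unlist(rows)
  if (!is.na(ntax) && length(out) != ntax)
    stop(sprintf("NEXUS parse error: NTAX=%d but %d taxa in MATRIX",
                 ntax, length(out)))
  if (length(unique(nchar(out))) != 1)
    stop("NEXUS parse error: unequal row lengths in MATRIX")
  if (!is.na(nchar_exp) && nchar(out[1]) != nchar_exp)
    stop(sprintf("NEXUS parse error: NCHAR=%d but rows have %d columns",
                 nchar_exp, nchar(out[1])))
  out
}

.parse_nexus_trees <- function(body) {
  translate <- NULL
  tm <- regexpr("(?i)translate\\b", body, perl = TRUE)
  if (tm != -1) {
    rest <- substr(body, tm + attr(tm, "match.length"), nchar(body))
    semi <- regexpr(";", rest, fixed = TRUE)
    if (semi == -1) stop("NEXUS parse error: TRANSLATE not terminated")
    entries <- strsplit(substr(rest, 1, semi - 1), ",")[[1]]
    translate <- list()
    for (e in entries) {
      toks <- strsplit(trimws(e), "\\s+")[[1]]
      if (length(toks) >= 2)
        translate[[toks[1]]] <- gsub("^['\"]|['\"]$", "", toks[2])
    }
  }
  trees <- list()
  tpos <- gregexpr("(?i)\\btree\\s+[^=]+=", body, perl = TRUE)[[1]]
  if (tpos[1] == -1) return(trees)
  lens <- attr(tpos, "match.length")
  for (i in seq_along(tpos)) {
    rest <- substr(body, tpos[i] + lens[i], nchar(body))
    semi <- regexpr(";", rest, fixed = TRUE)
    if (semi == -1) stop("NEXUS parse error: TREE not terminated")
    nwk <- trimws(substr(rest, 1, semi))
    nwk <- sub("^\\s*\\&?\\s*", "", sub("^\\s*\\[?&[RU]\\]?\\s*", "", nwk))
    tr <- read_newick(nwk)
    if (!is.null(translate)) {
      hit <- match(tr$tip.label, names(translate))
      tr$tip.label[!is.na(hit)] <-
        unlist(translate)[hit[!is.na(hit)]]
    }
    trees[[length(trees) + 1L]] <- tr
  }
  trees
}

#' Read a TSV table
#'
#' UTF-8, tab-separated, mandatory header row.
#'
#' @param path File path.
#' @return data.frame (strings kept as character).
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    check.names = FALSE)
}

#' Write a TSV table
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
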