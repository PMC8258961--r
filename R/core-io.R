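#' Construct a protein association network
#'
#' An association network is an undirected, confidence-weighted graph over
#' protein accessions. Edges are stored canonically (endpoint `a` sorts
#' before `b`), self-loops are dropped, and duplicate undirected edges are
#' collapsed keeping the maximum confidence.
#'
#' @param edges Data frame with columns `a`, `b` (accessions) and
#'   `confidence` (numeric in \[0, 1\]); an optional `channels` column
#'   carries comma-separated evidence tokens.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node accessions.
#' @return An object of class `assoc_network`: a list with `edges` (the
#'   canonical edge table) and `nodes` (all node accessions). Attributes
#'   `n_self_loops` and `n_duplicates` record how many rows were dropped or
#'   merged during canonicalization.
#' @export
assoc_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    stopifnot(all(c("a", "b", "confidence") %in% names(edges)))
    edges$a <- as.character(edges$a)
    edges$b <- as.character(edges$b)
    edges$confidence <- as.numeric(edges$confidence)
    if (any(!is.finite(edges$confidence)) ||
        any(edges$confidence < 0 | edges$confidence > 1)) {
      stop("edge confidence must lie in [0, 1]", call. = FALSE)
    }
  } else {
    edges <- data.frame(a = character(), b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  }
  loops <- edges$a == edges$b
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  if (nrow(edges) > 0) {
    lo <- pmin(edges$a, edges$b)
    hi <- pmax(edges$a, edges$b)
    edges$a <- lo
    edges$b <- hi
    key <- paste(lo, hi, sep = "\r")
    n_dup <- nrow(edges) - length(unique(key))
    if (n_dup > 0) {
      ord <- order(key, -edges$confidence)
      edges <- edges[ord, , drop = FALSE]
      edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    }
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    n_dup <- 0L
  }
  all_nodes <- sort(unique(c(edges$a, edges$b, as.character(nodes))))
  structure(
    list(edges = edges, nodes = all_nodes),
    n_self_loops = n_loops, n_duplicates = n_dup,
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Association network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) {
    cat("  confidence range:",
        sprintf("[%.3f, %.3f]", min(x$edges$confidence),
                max(x$edges$confidence)), "\n")
  }
  invisible(x)
}

#' Node degrees of an association network
#'
#' @param network An [assoc_network()].
#' @param min_confidence Count only edges at or above this confidence.
#' @return Named integer vector of degrees over all nodes (isolated nodes
#'   included with degree 0), in node order.
#' @export
network_degrees <- function(network, min_confidence = 0) {
  stopifnot(inherits(network, "assoc_network"))
  ed <- network$edges[network$edges$confidence >= min_confidence, , drop = FALSE]
  deg <- table(factor(c(ed$a, ed$b), levels = network$nodes))
  stats::setNames(as.integer(deg), network$nodes)
}

#' Induced subgraph on a node set
#'
#' @param network An [assoc_network()].
#' @param keep Character vector of accessions to retain.
#' @return An [assoc_network()] restricted to `keep` (edges with both
#'   endpoints retained; `keep` nodes absent from the network are dropped).
#' @export
restrict_network <- function(network, keep) {
  stopifnot(inherits(network, "assoc_network"))
  keep <- unique(as.character(keep))
  ed <- network$edges
  ed <- ed[ed$a %in% keep & ed$b %in% keep, , drop = FALSE]
  assoc_network(ed, nodes = intersect(network$nodes, keep))
}

#' Convert an association network to an igraph object
#'
#' @param network An [assoc_network()].
#' @param min_confidence Keep only edges at or above this confidence.
#' @return An undirected [igraph::graph] with edge attribute `confidence`.
#' @export
as_igraph <- function(network, min_confidence = 0) {
  stopifnot(inherits(network, "assoc_network"))
  ed <- network$edges[network$edges$confidence >= min_confidence, , drop = FALSE]
  igraph::graph_from_data_frame(
    ed[, c("a", "b", "confidence")], directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Read an association table in STRING protein-links dialect
#'
#' Parses a whitespace- or tab-delimited table of `node node score` rows
#' (a header line is detected and skipped). STRING distributes combined
#' scores in permille (integers 0-1000); such files are detected under
#' `score_dialect = "auto"` (all scores whole-numbered and any score > 1)
#' and rescaled to fractions. Duplicate undirected rows are collapsed
#' keeping the maximum confidence; self-loops are dropped with a warning.
#'
#' @param path Path to the table.
#' @param score_dialect `"auto"` (default), `"fraction"` (scores already in
#'   \[0, 1\]), or `"permille"` (integer scores in \[0, 1000\]).
#' @return An [assoc_network()].
#' @export
read_association_table <- function(path,
                                   score_dialect = c("auto", "fraction", "permille")) {
  score_dialect <- match.arg(score_dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty association table: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  first <- fields[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) {
    stop("association table has a header but no data rows: ", path, call. = FALSE)
  }
  a <- character(); b <- character(); score <- numeric()
  n <- length(fields) - start + 1L
  a <- vector("character", n); b <- vector("character", n)
  score <- vector("numeric", n)
  for (i in seq_len(n)) {
    f <- fields[[start + i - 1L]]
    line_no <- start + i - 1L
    if (length(f) < 3) {
      stop("malformed association row at line ", line_no,
           ": expected at least 3 fields", call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s)) {
      stop("malformed association row at line ", line_no,
           ": score '", f[3], "' is not numeric", call. = FALSE)
    }
    a[i] <- f[1]; b[i] <- f[2]; score[i] <- s
  }
  if (score_dialect == "auto") {
    score_dialect <- if (all(score == round(score)) && any(score > 1)) {
      "permille"
    } else {
      "fraction"
    }
  }
  if (score_dialect == "permille") {
    if (any(score < 0 | score > 1000)) {
      stop("permille scores must lie in [0, 1000]", call. = FALSE)
    }
    score <- score / 1000
  } else if (any(score < 0 | score > 1)) {
    stop("fraction scores must lie in [0, 1]", call. = FALSE)
  }
  net <- assoc_network(data.frame(a = a, b = b, confidence = score,
                                  stringsAsFactors = FALSE))
  if (attr(net, "n_self_loops") > 0) {
    warning("dropped ", attr(net, "n_self_loops"), " self-loop row(s) in ",
            path, call. = FALSE)
  }
  net
}

#' Read a seed panel
#'
#' A seed panel lists the causative proteins the interactome is grown from:
#' one row per protein with its gene symbol, protein accession, and the
#' syndromes it is assigned to (semicolon-separated tokens). An optional
#' `group` column records display-only node groupings (e.g. a RAS node
#' standing for HRAS/KRAS/NRAS); groups are expanded to member accessions
#' at load time and analyses always run on members.
#'
#' @param path CSV with columns `gene_symbol`, `accession`, `syndromes`
#'   and optionally `group`.
#' @param vocabulary Accepted syndrome tokens
#'   (default [rasopathy_syndromes()]).
#' @return A `seed_panel`: a data frame with columns `accession`,
#'   `gene_symbol` and list-column `syndromes`, with attribute `aliases`
#'   (named list mapping group label to member accessions).
#' @export
read_seed_panel <- function(path, vocabulary = rasopathy_syndromes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("gene_symbol", "accession", "syndromes")
  if (!all(required %in% names(df))) {
    stop("seed panel must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df$accession <- trimws(df$accession)
  if (any(!nzchar(df$accession))) stop("empty accession in seed panel", call. = FALSE)
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in seed panel: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df$syndromes[is.na(df$syndromes)] <- ""
  syn <- strsplit(df$syndromes, ";", fixed = TRUE)
  syn <- lapply(syn, function(s) unique(trimws(s[nzchar(trimws(s))])))
  empty <- vapply(syn, length, 1L) == 0
  if (any(empty)) {
    stop("seed(s) without syndrome assignment: ",
         paste(df$accession[empty], collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(unlist(syn)), vocabulary)
  if (length(bad) > 0) {
    stop("unknown syndrome token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aliases <- list()
  if ("group" %in% names(df)) {
    grp <- trimws(df$group)
    grp[is.na(grp)] <- ""
    for (g in unique(grp[nzchar(grp)])) {
      aliases[[g]] <- df$accession[grp == g]
    }
  }
  panel <- data.frame(accession = df$accession,
                      gene_symbol = df$gene_symbol,
                      stringsAsFactors = FALSE)
  panel$syndromes <- syn
  structure(panel, aliases = aliases, class = c("seed_panel", "data.frame"))
}

#' @export
print.seed_panel <- function(x, ...) {
  cat("Seed panel:", nrow(x), "proteins,",
      length(unique(unlist(x$syndromes))), "syndromes\n")
  al <- attr(x, "aliases")
  if (length(al) > 0) {
    cat("  display groups:", paste(names(al), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Packaged RASopathy seed panels
#'
#' The curated panel of the 27 causative RASopathy proteins (gene symbol,
#' UniProt accession, syndrome assignments), and the extended 32-protein
#' panel that additionally carries the five diagnostic-panel genes
#' ANKRD11, FGFR3, MEF2C, SHOX and SRCAP.
#'
#' @param extended If `TRUE`, return the 32-protein extended panel.
#' @return A `seed_panel` (see [read_seed_panel()]).
#' @export
default_seed_panel <- function(extended = FALSE) {
  f <- if (extended) "seed_panel_extended.csv" else "seed_panel.csv"
  read_seed_panel(system.file("extdata", f, package = "rasonet",
                              mustWork = TRUE))
}

#' Read a phosphosite dysregulation table
#'
#' One row per reported phosphosite measurement: the protein it was
#' observed on (in source-organism coordinates), the site, the fold change
#' of the normalized phospho-signal versus control (quantitative entries)
#' or a reported direction (qualitative immunoblot entries), the assay
#' class, the syndrome, and the study it came from. Undefined phosphosites
#' (known phosphorylation, unknown residue position) may leave `residue`
#' and `position` empty; they are excluded from coordinate mapping and the
#' dysregulation matrix but retained for direction tallies.
#'
#' Repeated quantitative reports of the same (protein, site, syndrome)
#' from different studies receive prime replicate tags (`'`, `''`, ...)
#' so they remain distinct matrix rows.
#'
#' @param path CSV with columns `accession`, `gene_symbol`, `organism`,
#'   `residue`, `position`, `fold_change`, `direction`, `assay`,
#'   `syndrome`, `study_ref`.
#' @param vocabulary Accepted syndrome tokens.
#' @return A data frame of validated records with the logical column
#'   `quantitative` and character column `replicate_tag` added.
#' @export
read_phospho_table <- function(path, vocabulary = rasopathy_syndromes()) {
  # read everything as character: a residue column of "T"s must not become
  # logical TRUE under read.csv's type sniffing
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("accession", "gene_symbol", "organism", "residue",
                "position", "fold_change", "direction", "assay",
                "syndrome", "study_ref")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("phosphosite table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$organism <- normalize_organism(df$organism)
  df$residue[!is.na(df$residue) & !nzchar(trimws(df$residue))] <- NA
  df$position <- suppressWarnings(as.integer(df$position))
  df$fold_change <- suppressWarnings(as.numeric(df$fold_change))
  df$direction[!is.na(df$direction) & !nzchar(trimws(df$direction))] <- NA

  has_site <- !is.na(df$position)
  bad_res <- has_site & (is.na(df$residue) | !df$residue %in% c("S", "T", "Y"))
  if (any(bad_res)) {
    stop("row(s) ", paste(which(bad_res), collapse = ", "),
         ": residue must be one of S, T, Y for positioned sites",
         call. = FALSE)
  }
  if (any(has_site & df$position < 1L)) {
    stop("site positions must be >= 1", call. = FALSE)
  }
  quant <- !is.na(df$fold_change)
  if (any(quant & df$fold_change <= 0)) {
    stop("row(s) ", paste(which(quant & df$fold_change <= 0), collapse = ", "),
         ": fold_change must be > 0", call. = FALSE)
  }
  no_dir <- !quant & is.na(df$direction)
  if (any(no_dir)) {
    stop("row(s) ", paste(which(no_dir), collapse = ", "),
         ": need either fold_change or direction", call. = FALSE)
  }
  bad_dir <- !is.na(df$direction) & !df$direction %in% c("up", "down", "unchanged")
  if (any(bad_dir)) {
    stop("direction must be one of up, down, unchanged", call. = FALSE)
  }
  if (any(!df$assay %in% c("MS", "immunoblot"))) {
    stop("assay must be 'MS' or 'immunoblot'", call. = FALSE)
  }
  bad_syn <- setdiff(unique(df$syndrome), vocabulary)
  if (length(bad_syn) > 0) {
    stop("unknown syndrome token(s): ", paste(bad_syn, collapse = ", "),
         call. = FALSE)
  }
  df$quantitative <- quant
  df <- assign_replicate_tags(df,
                              key_cols = c("accession", "residue",
                                           "position", "syndrome"))
  class(df) <- c("phospho_records", "data.frame")
  df
}

#' Assign prime replicate tags to repeated site measurements
#'
#' Quantitative re-measurements of the same site in the same syndrome by
#' different studies are kept as separate rows; the second and later
#' occurrences are tagged with prime marks (`'`, `''`, ...) in order of
#' appearance so that matrix row labels stay unique.
#'
#' @param records Phosphosite record data frame.
#' @param key_cols Columns identifying "the same site in the same
#'   syndrome"; pass human-coordinate columns after ortholog mapping.
#' @return `records` with a `replicate_tag` character column (re)computed.
#' @export
assign_replicate_tags <- function(records,
                                  key_cols = c("accession", "residue",
                                               "position", "syndrome")) {
  if (!"quantitative" %in% names(records)) {
    records$quantitative <- !is.na(records$fold_change)
  }
  key <- do.call(paste, c(records[key_cols], sep = "\r"))
  key[!records$quantitative] <- paste0(key[!records$quantitative], "\rqual",
                                       seq_len(sum(!records$quantitative)))
  occ <- stats::ave(seq_along(key), key, FUN = seq_along)
  records$replicate_tag <- strrep("'", occ - 1L)
  records
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is the representation the site-mapping functions consume.
#'
#' @param path FASTA file path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()`: named character vector (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[\t ]+"), `[`, "", 1L)
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write annotation sets in GMT format
#'
#' One annotation term per line: term id, term name, then member
#' accessions, all tab-separated.
#'
#' @param path GMT file path.
#' @param sets List of annotation sets, each a list with `term_id`,
#'   `term_name`, and character vector `members`.
#' @return `read_gmt()`: a list of annotation sets as above.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": need term id, name, >= 1 member",
           call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    list(term_id = f[1], term_name = f[2], members = members)
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write and read result tables as TSV
#'
#' All pipeline outputs are UTF-8 tab-separated tables with a header row,
#' `NA` for missing values, and no quoting or row names, so that a write
#' followed by a read reproduces the table exactly.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `read_tsv()`: the data frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname write_tsv
#' @param x Object serializable by jsonlite.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
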