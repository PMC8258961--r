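#' Map a phosphosite onto a human ortholog sequence
#'
#' Transfers a 1-based site coordinate from a source-organism sequence to
#' its human ortholog by global (Needleman-Wunsch) pairwise alignment with
#' the BLOSUM62 substitution matrix and affine gap costs. The human
#' position aligned opposite the source site is returned; it must carry a
#' phospho-acceptor residue (S, T or Y). An identical residue is the
#' normal case; a conservative S/T exchange is accepted and flagged. A
#' site aligned opposite a gap or a non-acceptor residue yields an
#' unmapped result with a reason, not an error.
#'
#' @param source_seq Source-organism protein sequence (character scalar).
#' @param human_seq Human protein sequence.
#' @param site Site in `"Y241"` notation (or a list with `residue` and
#'   `position` as from [parse_site()]). The source sequence must carry
#'   the stated residue at the stated position.
#' @param gap_opening,gap_extension Affine gap costs for the alignment
#'   (defaults 10 and 0.5).
#' @return A list with `mapped` (logical), `human_residue`,
#'   `human_position`, `human_site` (rendered notation or `NA`),
#'   `conservative` (S/T exchange flag), `reason` (`NA` when mapped, else
#'   `"gap"` or `"non_acceptor"`), and `score` (alignment score).
#' @examples
#' map_site_to_human("MKSYR", "MKSYR", "Y4")
#' @export
map_site_to_human <- function(source_seq, human_seq, site,
                              gap_opening = 10, gap_extension = 0.5) {
  if (is.character(site)) site <- parse_site(site)
  stopifnot(is.character(source_seq), nzchar(source_seq),
            is.character(human_seq), nzchar(human_seq))
  if (site$position > nchar(source_seq)) {
    stop("site position ", site$position, " beyond source sequence length ",
         nchar(source_seq), call. = FALSE)
  }
  at <- substr(source_seq, site$position, site$position)
  if (at != site$residue) {
    stop("source sequence carries '", at, "' at position ", site$position,
         ", not '", site$residue, "'", call. = FALSE)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(source_seq), Biostrings::AAString(human_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  src_idx <- cumsum(p != "-")
  hum_idx <- cumsum(s != "-")
  col <- which(src_idx == site$position & p != "-")[1]
  res <- list(mapped = FALSE, human_residue = NA_character_,
              human_position = NA_integer_, human_site = NA_character_,
              conservative = FALSE, reason = NA_character_,
              score = Biostrings::score(al),
              source_site = render_site(site$residue, site$position))
  if (s[col] == "-") {
    res$reason <- "gap"
    return(res)
  }
  hres <- s[col]
  if (!hres %in% c("S", "T", "Y")) {
    res$reason <- "non_acceptor"
    res$human_residue <- hres
    res$human_position <- hum_idx[col]
    return(res)
  }
  res$mapped <- TRUE
  res$human_residue <- hres
  res$human_position <- hum_idx[col]
  res$human_site <- render_site(hres, hum_idx[col])
  res$conservative <- hres != site$residue
  res
}

#' Harmonize phosphosite records to human coordinates
#'
#' Resolves every record of a phosphosite table to a human protein and
#' site. Human-organism records map to themselves (identity); records
#' from model organisms are paired with their human ortholog through an
#' explicit ortholog table and their site coordinate is transferred with
#' [map_site_to_human()]. Records that cannot be resolved (no ortholog
#' entry, missing sequence, undefined site position, residue mismatch, or
#' a site aligned to a gap/non-acceptor) are retained with `mapped =
#' FALSE` and a reason; they are excluded from the dysregulation matrix
#' but still feed direction tallies. Replicate prime tags are recomputed
#' on human coordinates so that the same human site measured through
#' different organisms is tagged consistently.
#'
#' @param records Phosphosite records from [read_phospho_table()].
#' @param sequences Named character vector of protein sequences covering
#'   the source and human accessions involved (see [read_fasta()]).
#' @param orthologs Data frame with columns `accession` (source) and
#'   `human_accession`, optionally `human_gene_symbol`. May be `NULL`
#'   when all records are human.
#' @return The records with columns `human_accession`, `human_name`,
#'   `human_residue`, `human_position`, `mapped`, `map_reason`,
#'   `map_conservative` added and `replicate_tag` recomputed.
#' @export
map_records_to_human <- function(records, sequences = NULL, orthologs = NULL) {
  n <- nrow(records)
  records$human_accession <- NA_character_
  records$human_name <- NA_character_
  records$human_residue <- NA_character_
  records$human_position <- NA_integer_
  records$mapped <- FALSE
  records$map_reason <- NA_character_
  records$map_conservative <- FALSE
  for (i in seq_len(n)) {
    org <- records$organism[i]
    acc <- records$accession[i]
    if (org == "human") {
      hacc <- acc
      hname <- records$gene_symbol[i]
    } else {
      if (is.null(orthologs) || !acc %in% orthologs$accession) {
        records$map_reason[i] <- "no_ortholog"
        next
      }
      j <- match(acc, orthologs$accession)
      hacc <- orthologs$human_accession[j]
      hname <- if ("human_gene_symbol" %in% names(orthologs) &&
                   !is.na(orthologs$human_gene_symbol[j])) {
        orthologs$human_gene_symbol[j]
      } else {
        records$gene_symbol[i]
      }
    }
    records$human_accession[i] <- hacc
    records$human_name[i] <- hname
    if (is.na(records$position[i])) {
      records$map_reason[i] <- "undefined_site"
      next
    }
    if (org == "human") {
      # identity mapping; verify against the sequence when we have it
      if (!is.null(sequences) && acc %in% names(sequences)) {
        at <- substr(sequences[[acc]], records$position[i],
                     records$position[i])
        if (at != records$residue[i]) {
          records$map_reason[i] <- "residue_mismatch"
          next
        }
      }
      records$human_residue[i] <- records$residue[i]
      records$human_position[i] <- records$position[i]
      records$mapped[i] <- TRUE
      next
    }
    if (is.null(sequences) || !acc %in% names(sequences) ||
        !hacc %in% names(sequences)) {
      records$map_reason[i] <- "no_sequence"
      next
    }
    src_seq <- sequences[[acc]]
    at <- substr(src_seq, records$position[i], records$position[i])
    if (records$position[i] > nchar(src_seq) || at != records$residue[i]) {
      records$map_reason[i] <- "residue_mismatch"
      next
    }
    m <- map_site_to_human(src_seq, sequences[[hacc]],
                           list(residue = records$residue[i],
                                position = records$position[i]))
    if (m$mapped) {
      records$human_residue[i] <- m$human_residue
      records$human_position[i] <- m$human_position
      records$mapped[i] <- TRUE
      records$map_conservative[i] <- m$conservative
    } else {
      records$map_reason[i] <- m$reason
    }
  }
  n_unmapped <- sum(!records$mapped & records$quantitative)
  if (n_unmapped > 0) {
    message(n_unmapped, " quantitative record(s) could not be mapped to ",
            "human coordinates")
  }
  assign_replicate_tags(records,
                        key_cols = c("human_accession", "human_residue",
                                     "human_position", "syndrome"))
}

#' Normalized phospho-signal fold change
#'
#' Phosphorylation levels are normalized to the total abundance of the
#' phosphoprotein in each condition before the disease/control ratio is
#' taken, harmonizing measurements across experimental models:
#' `(phospho_disease / total_disease) / (phospho_control / total_control)`.
#'
#' @param phospho_disease,total_disease Phospho-signal and total protein
#'   abundance in the disease model (positive).
#' @param phospho_control,total_control Same for the control.
#' @return The normalized fold change (positive scalar).
#' @examples
#' normalize_fold_change(4, 2, 1, 1)  # 2
#' @export
normalize_fold_change <- function(phospho_disease, total_disease,
                                  phospho_control, total_control) {
  vals <- c(phospho_disease, total_disease, phospho_control, total_control)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all abundances must be positive", call. = FALSE)
  }
  (phospho_disease / total_disease) / (phospho_control / total_control)
}

#' Partition records by the dysregulation threshold
#'
#' Quantitative records are called up when the fold change is at or above
#' the threshold, down when at or below its reciprocal (symmetric on the
#' log scale; both boundaries inclusive), and not dysregulated in
#' between. Qualitative (direction-only) records pass through on their
#' stated direction. A `reported_unchanged` flag marks measurements that
#' were made but showed no alteration -- a quantitative value inside the
#' threshold band, or an explicit "unchanged" direction -- as opposed to
#' sites that were simply not measured.
#'
#' @param records Phosphosite records.
#' @param threshold Fold-change threshold (> 1; default 1.5).
#' @return The records with columns `status` (`"up"`, `"down"`,
#'   `"not_dysregulated"`) and `reported_unchanged` added.
#' @export
apply_threshold <- function(records, threshold = 1.5) {
  if (!is.numeric(threshold) || threshold <= 1) {
    stop("threshold must be > 1", call. = FALSE)
  }
  fc <- records$fold_change
  status <- rep("not_dysregulated", nrow(records))
  status[records$quantitative & fc >= threshold] <- "up"
  status[records$quantitative & fc <= 1 / threshold] <- "down"
  qual <- !records$quantitative
  status[qual & records$direction == "up"] <- "up"
  status[qual & records$direction == "down"] <- "down"
  records$status <- status
  records$reported_unchanged <-
    (records$quantitative & status == "not_dysregulated") |
    (qual & records$direction == "unchanged")
  attr(records, "threshold") <- threshold
  records
}

#' Build the site-by-syndrome dysregulation matrix
#'
#' Rows are human phosphosites (labelled `PROTEIN:SITE`, with prime tags
#' for replicate measurements from different studies), columns are
#' syndromes. A cell holds the log2 fold change of a quantitative record
#' passing the threshold, the reported-unchanged state (rendered `0*`)
#' for a measurement that showed no alteration, or missing when no data
#' exist. Only mapped quantitative records enter the matrix; qualitative
#' records feed the direction tallies instead.
#'
#' @param records Mapped phosphosite records (see
#'   [map_records_to_human()]).
#' @param threshold Fold-change threshold (default 1.5).
#' @param syndromes Optional column order; defaults to the sorted
#'   syndromes present.
#' @return A `dysreg_matrix`: list with numeric matrix `log2fc` (NA =
#'   missing), logical matrix `unchanged`, and `threshold`.
#' @export
build_matrix <- function(records, threshold = 1.5, syndromes = NULL) {
  if (!"status" %in% names(records)) {
    records <- apply_threshold(records, threshold)
  }
  use <- records$quantitative & records$mapped
  rec <- records[use, , drop = FALSE]
  name <- ifelse(is.na(rec$human_name) | !nzchar(rec$human_name),
                 rec$human_accession, rec$human_name)
  label <- paste0(name, ":",
                  mapply(render_site, rec$human_residue, rec$human_position),
                  rec$replicate_tag)
  cols <- if (is.null(syndromes)) sort(unique(rec$syndrome)) else syndromes
  rows <- unique(label)
  log2fc <- matrix(NA_real_, length(rows), length(cols),
                   dimnames = list(rows, cols))
  unchanged <- matrix(FALSE, length(rows), length(cols),
                      dimnames = list(rows, cols))
  for (i in seq_len(nrow(rec))) {
    r <- label[i]; cl <- rec$syndrome[i]
    if (!cl %in% cols) next
    if (!is.na(log2fc[r, cl]) || unchanged[r, cl]) {
      warning("duplicate cell for ", r, " / ", cl,
              "; keeping the first value", call. = FALSE)
      next
    }
    if (rec$status[i] %in% c("up", "down")) {
      log2fc[r, cl] <- log2(rec$fold_change[i])
    } else {
      unchanged[r, cl] <- TRUE
    }
  }
  structure(list(log2fc = log2fc, unchanged = unchanged,
                 threshold = threshold),
            class = "dysreg_matrix")
}

#' Render a dysregulation matrix for export
#'
#' @param x A `dysreg_matrix`.
#' @param ... Unused.
#' @return A data frame with a leading `site` column and one character
#'   column per syndrome: formatted log2 fold changes, `0*` for
#'   reported-unchanged cells, `NA` for missing cells.
#' @export
as.data.frame.dysreg_matrix <- function(x, ...) {
  out <- matrix(NA_character_, nrow(x$log2fc), ncol(x$log2fc),
                dimnames = dimnames(x$log2fc))
  num <- !is.na(x$log2fc)
  out[num] <- formatC(x$log2fc[num], format = "g", digits = 6)
  out[x$unchanged] <- "0*"
  out[is.na(out)] <- "NA"
  data.frame(site = rownames(out), out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.dysreg_matrix <- function(x, ...) {
  cat("Dysregulation matrix:", nrow(x$log2fc), "sites x",
      ncol(x$log2fc), "syndromes;",
      sum(!is.na(x$log2fc)), "log2fc cells,",
      sum(x$unchanged), "reported-unchanged cells\n")
  invisible(x)
}

#' Assign two-syndrome dysregulation clusters
#'
#' Compares every matrix row across two syndrome columns (NS and NSML by
#' default) and labels it: `a` = upregulated in both, `b` = downregulated
#' in both, `c` = dysregulated in the first syndrome only (second missing
#' or reported-unchanged), `d` = dysregulated in the second only, and
#' `discordant` = dysregulated in opposite directions (kept apart from
#' the four concordant clusters). Rows dysregulated in neither column are
#' dropped.
#'
#' @param matrix A `dysreg_matrix` from [build_matrix()].
#' @param cols Length-2 character vector of syndrome columns.
#' @return Data frame with columns `site` and `cluster`.
#' @export
assign_clusters <- function(matrix, cols = c("NS", "NSML")) {
  stopifnot(inherits(matrix, "dysreg_matrix"), length(cols) == 2)
  miss <- setdiff(cols, colnames(matrix$log2fc))
  if (length(miss) > 0) {
    stop("matrix lacks syndrome column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v1 <- matrix$log2fc[, cols[1]]
  v2 <- matrix$log2fc[, cols[2]]
  d1 <- !is.na(v1)
  d2 <- !is.na(v2)
  cluster <- rep(NA_character_, nrow(matrix$log2fc))
  cluster[d1 & d2 & v1 > 0 & v2 > 0] <- "a"
  cluster[d1 & d2 & v1 < 0 & v2 < 0] <- "b"
  cluster[d1 & d2 & sign(v1) != sign(v2)] <- "discordant"
  cluster[d1 & !d2] <- "c"
  cluster[!d1 & d2] <- "d"
  keep <- !is.na(cluster)
  data.frame(site = rownames(matrix$log2fc)[keep],
             cluster = cluster[keep],
             stringsAsFactors = FALSE)
}

#' Summarize dysregulation by syndrome
#'
#' Per syndrome: the number of distinct dysregulated sites and proteins
#' (quantitative, and including qualitative direction calls), the record
#' counts of up- and downregulation under both tallies, the mean raw fold
#' changes of up and down records, and the extreme sites. Global up/down
#' counts over all syndromes (a site counted once per syndrome entry) are
#' attached as attribute `totals`, again under both tallies since
#' immunoblot direction calls can be included or not.
#'
#' @param records Phosphosite records; [apply_threshold()] is applied
#'   with `threshold` if the `status` column is absent.
#' @param threshold Fold-change threshold (default 1.5).
#' @return Data frame with one row per syndrome; attribute `totals` is a
#'   list with `n_up_quant`, `n_down_quant`, `n_up_all`, `n_down_all`.
#' @export
summarize_by_syndrome <- function(records, threshold = 1.5) {
  if (!"status" %in% names(records)) {
    records <- apply_threshold(records, threshold)
  }
  prot <- if ("human_accession" %in% names(records)) {
    ifelse(is.na(records$human_accession), records$accession,
           records$human_accession)
  } else {
    records$accession
  }
  pos <- if ("human_position" %in% names(records) &&
             any(!is.na(records$human_position))) {
    ifelse(is.na(records$human_position), records$position,
           records$human_position)
  } else {
    records$position
  }
  # undefined sites cannot be merged; key them by row so each counts once
  site_key <- paste(prot, records$residue, pos)
  site_key[is.na(pos)] <- paste0("row", which(is.na(pos)))
  dys <- records$status %in% c("up", "down")
  quant <- records$quantitative
  syndromes <- sort(unique(records$syndrome))
  rows <- lapply(syndromes, function(s) {
    in_s <- records$syndrome == s
    dq <- in_s & dys & quant
    da <- in_s & dys
    up_q <- in_s & quant & records$status == "up"
    dn_q <- in_s & quant & records$status == "down"
    fc <- records$fold_change
    sel <- in_s & quant & dys
    max_i <- if (any(sel)) which(sel)[which.max(fc[which(sel)])] else NA
    min_i <- if (any(sel)) which(sel)[which.min(fc[which(sel)])] else NA
    lab <- function(i) {
      if (is.na(i)) return(NA_character_)
      nm <- if ("human_name" %in% names(records) &&
                !is.na(records$human_name[i])) {
        records$human_name[i]
      } else {
        records$gene_symbol[i]
      }
      st <- if (!is.na(pos[i])) {
        render_site(records$residue[i], pos[i])
      } else {
        "?"
      }
      paste0(nm, ":", st)
    }
    data.frame(
      syndrome = s,
      n_sites_quant = length(unique(site_key[dq])),
      n_proteins_quant = length(unique(prot[dq])),
      n_sites_all = length(unique(site_key[da])),
      n_proteins_all = length(unique(prot[da])),
      n_up_quant = sum(up_q),
      n_down_quant = sum(dn_q),
      n_up_all = sum(in_s & records$status == "up"),
      n_down_all = sum(in_s & records$status == "down"),
      mean_fc_up = if (any(up_q)) mean(fc[up_q]) else NA_real_,
      mean_fc_down = if (any(dn_q)) mean(fc[dn_q]) else NA_real_,
      max_site = lab(max_i),
      max_fc = if (is.na(max_i)) NA_real_ else fc[max_i],
      min_site = lab(min_i),
      min_fc = if (is.na(min_i)) NA_real_ else fc[min_i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(syndrome = character(), n_sites_quant = integer(),
                      n_proteins_quant = integer(), n_sites_all = integer(),
                      n_proteins_all = integer(), n_up_quant = integer(),
                      n_down_quant = integer(), n_up_all = integer(),
                      n_down_all = integer(), mean_fc_up = numeric(),
                      mean_fc_down = numeric(), max_site = character(),
                      max_fc = numeric(), min_site = character(),
                      min_fc = numeric(), stringsAsFactors = FALSE)
  }
  sk_syn <- paste(site_key, records$syndrome)
  totals <- list(
    n_up_quant = length(unique(sk_syn[quant & records$status == "up"])),
    n_down_quant = length(unique(sk_syn[quant & records$status == "down"])),
    n_up_all = length(unique(sk_syn[records$status == "up"])),
    n_down_all = length(unique(sk_syn[records$status == "down"]))
  )
  attr(out, "totals") <- totals
  out
}

#' Restrict phosphosite records to the interactome
#'
#' Keeps records whose (human) protein belongs to the interactome, i.e.
#' to the union of all neighbor sets plus the seeds themselves, and
#' counts the distinct phosphoproteins retained.
#'
#' @param records Phosphosite records (mapped if cross-organism).
#' @param interactome An `interactome` from [build_interactome()].
#' @return A list with `records` (the filtered table) and
#'   `n_phosphoproteins` (distinct retained protein accessions).
#' @export
crosslink_interactome <- function(records, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  space <- union(interactome$unique_union, interactome$seeds)
  prot <- if ("human_accession" %in% names(records)) {
    ifelse(is.na(records$human_accession), records$accession,
           records$human_accession)
  } else {
    records$accession
  }
  keep <- prot %in% space
  list(records = records[keep, , drop = FALSE],
       n_phosphoproteins = length(unique(prot[keep])))
}
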