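#' Read a phosphosite catalog
#'
#' A catalog row documents one literature reference class for a site on a
#' protein: the protein accession, the site (residue and position), the
#' throughput class of the supporting references -- LTP (low-throughput,
#' targeted assays) or HTP (high-throughput MS screening) -- and how many
#' references of that class exist.
#'
#' @param path CSV with columns `protein`, `residue`, `position`,
#'   `ref_class` (LTP or HTP), `ref_count`.
#' @return Validated data frame.
#' @export
read_phospho_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("protein", "residue", "position", "ref_class", "ref_count")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("catalog missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df$ref_count <- as.integer(df$ref_count)
  if (any(!df$residue %in% c("S", "T", "Y"))) {
    stop("catalog residues must be S, T or Y", call. = FALSE)
  }
  if (any(!df$ref_class %in% c("LTP", "HTP"))) {
    stop("catalog ref_class must be LTP or HTP", call. = FALSE)
  }
  if (any(is.na(df$ref_count) | df$ref_count < 0)) {
    stop("catalog ref_count must be a non-negative integer", call. = FALSE)
  }
  df
}

#' Per-protein phosphosite census
#'
#' Counts the distinct catalogued phosphosites of every panel protein
#' (site identity is residue plus position; a site with many references
#' counts once) and splits the supporting references into low- and
#' high-throughput classes. Catalog rows for proteins outside the panel
#' are skipped with a warning. Proteins reaching a site-count threshold
#' are flagged and their summed site count reported, mirroring the
#' heavily-phosphorylated subgroup of the panel.
#'
#' @param catalog Catalog data frame (see [read_phospho_catalog()]).
#' @param panel A `seed_panel`.
#' @param min_sites_flag Site count at which a protein is flagged as
#'   heavily phosphorylated (default 20).
#' @return A `phospho_census`: list with `entries` (one row per panel
#'   protein with catalogued sites: `accession`, `gene_symbol`,
#'   `n_sites`, `n_ltp_refs`, `n_htp_refs`, `syndromes`), and `totals`
#'   (total sites; LTP/HTP reference totals and percentage split, both as
#'   reference counts and as site-reference rows; flagged proteins with
#'   their summed and remaining site counts; skipped row count).
#' @export
build_census <- function(catalog, panel, min_sites_flag = 20) {
  stopifnot(inherits(panel, "seed_panel"))
  in_panel <- catalog$protein %in% panel$accession
  n_skipped <- sum(!in_panel)
  if (n_skipped > 0) {
    warning(n_skipped, " catalog row(s) for proteins outside the panel ",
            "skipped", call. = FALSE)
  }
  cat_df <- catalog[in_panel, , drop = FALSE]
  prots <- sort(unique(cat_df$protein))
  entries <- do.call(rbind, lapply(prots, function(p) {
    rows <- cat_df[cat_df$protein == p, , drop = FALSE]
    data.frame(
      accession = p,
      gene_symbol = panel$gene_symbol[match(p, panel$accession)],
      n_sites = length(unique(paste(rows$residue, rows$position))),
      n_ltp_refs = sum(rows$ref_count[rows$ref_class == "LTP"]),
      n_htp_refs = sum(rows$ref_count[rows$ref_class == "HTP"]),
      syndromes = paste(panel$syndromes[[match(p, panel$accession)]],
                        collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(entries)) {
    entries <- data.frame(accession = character(), gene_symbol = character(),
                          n_sites = integer(), n_ltp_refs = integer(),
                          n_htp_refs = integer(), syndromes = character(),
                          stringsAsFactors = FALSE)
  }
  ltp_refs <- sum(entries$n_ltp_refs)
  htp_refs <- sum(entries$n_htp_refs)
  ltp_rows <- sum(cat_df$ref_class == "LTP")
  htp_rows <- sum(cat_df$ref_class == "HTP")
  flagged <- entries$accession[entries$n_sites >= min_sites_flag]
  totals <- list(
    n_sites_total = sum(entries$n_sites),
    ltp_refs = ltp_refs, htp_refs = htp_refs,
    ltp_pct = if (ltp_refs + htp_refs > 0) {
      100 * ltp_refs / (ltp_refs + htp_refs)
    } else {
      NA_real_
    },
    htp_pct = if (ltp_refs + htp_refs > 0) {
      100 * htp_refs / (ltp_refs + htp_refs)
    } else {
      NA_real_
    },
    ltp_site_rows = ltp_rows, htp_site_rows = htp_rows,
    flagged = flagged,
    min_sites_flag = min_sites_flag,
    flagged_site_sum = sum(entries$n_sites[entries$accession %in% flagged]),
    rest_site_sum = sum(entries$n_sites[!entries$accession %in% flagged]),
    n_skipped = n_skipped
  )
  structure(list(entries = entries, totals = totals),
            class = "phospho_census")
}

#' @export
print.phospho_census <- function(x, ...) {
  t <- x$totals
  cat("Phosphosite census:", nrow(x$entries), "proteins,",
      t$n_sites_total, "sites\n")
  if (t$ltp_refs + t$htp_refs > 0) {
    cat(sprintf("  references: %d LTP (%.1f%%), %d HTP (%.1f%%)\n",
                t$ltp_refs, t$ltp_pct, t$htp_refs, t$htp_pct))
  }
  cat("  proteins with >=", t$min_sites_flag, "sites:",
      length(t$flagged), "accounting for", t$flagged_site_sum, "sites\n")
  invisible(x)
}

#' Long-format bubble table of sites per (syndrome, protein)
#'
#' One row per (syndrome, protein) assignment in the panel, carrying the
#' protein's catalogued site count (0 when the census has none); proteins
#' assigned to several syndromes appear once per syndrome with the same
#' count. Per-syndrome protein counts are attached as attribute
#' `proteins_per_syndrome`.
#'
#' @param census A `phospho_census` from [build_census()].
#' @param panel A `seed_panel`.
#' @return Data frame with columns `syndrome`, `accession`,
#'   `gene_symbol`, `n_sites`.
#' @export
bubble_table <- function(census, panel) {
  stopifnot(inherits(census, "phospho_census"),
            inherits(panel, "seed_panel"))
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    acc <- panel$accession[i]
    n <- census$entries$n_sites[match(acc, census$entries$accession)]
    if (is.na(n)) n <- 0L
    for (syn in panel$syndromes[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        syndrome = syn, accession = acc,
        gene_symbol = panel$gene_symbol[i], n_sites = n,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$syndrome, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(out$syndrome)
  attr(out, "proteins_per_syndrome") <-
    stats::setNames(as.integer(counts), names(counts))
  out
}
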