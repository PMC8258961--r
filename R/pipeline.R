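#' Pipeline run configuration
#'
#' Collects input paths and analysis parameters for [run_all()]. Any
#' input path may be `NULL`; the stages that depend on it are then
#' skipped with a notice. Defaults: minimum association confidence
#' 0.700, hub multiplier 4, fold-change threshold 1.5, FDR cutoff 0.01.
#'
#' @param edges Association table path (STRING protein-links dialect).
#' @param panel Seed panel CSV path.
#' @param phospho Phosphosite dysregulation CSV path.
#' @param fasta FASTA path with source and human sequences.
#' @param orthologs Source-to-human ortholog pair TSV path.
#' @param catalog Phosphosite catalog CSV path.
#' @param gmt Annotation GMT path.
#' @param min_confidence Minimum association confidence.
#' @param hub_multiplier Hub cutoff multiple of the mean degree.
#' @param fc_threshold Fold-change dysregulation threshold.
#' @param fdr_cutoff Enrichment FDR cutoff.
#' @param cluster_cols Two syndromes compared by the cluster assignment.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(edges = NULL, panel = NULL, phospho = NULL,
                       fasta = NULL, orthologs = NULL, catalog = NULL,
                       gmt = NULL, min_confidence = 0.700,
                       hub_multiplier = 4, fc_threshold = 1.5,
                       fdr_cutoff = 0.01, cluster_cols = c("NS", "NSML"),
                       out_dir = NULL) {
  stopifnot(min_confidence >= 0, min_confidence <= 1,
            hub_multiplier > 0, fc_threshold > 1,
            fdr_cutoff > 0, fdr_cutoff <= 1,
            length(cluster_cols) == 2)
  structure(list(edges = edges, panel = panel, phospho = phospho,
                 fasta = fasta, orthologs = orthologs, catalog = catalog,
                 gmt = gmt, min_confidence = min_confidence,
                 hub_multiplier = hub_multiplier,
                 fc_threshold = fc_threshold, fdr_cutoff = fdr_cutoff,
                 cluster_cols = cluster_cols, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are available: interactome
#' construction with overlap, pairwise-intersection, syndrome-partition
#' and hub statistics; phosphosite harmonization to human coordinates
#' with interactome cross-linking, thresholding, dysregulation matrix
#' and two-syndrome clusters; the per-protein phosphosite census and
#' bubble table; and annotation over-representation of the dysregulated
#' phosphoproteins. Result tables are written as TSV (plus a
#' machine-readable `summary.json`) when the configuration names an
#' output directory.
#'
#' @param config A [run_config()] (or a directory path produced by
#'   [simulate_study()], in which case the standard file names are
#'   assumed).
#' @return A report bundle (list) with the per-stage results and a
#'   `summary` element (parameters plus per-stage row counts).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1 && dir.exists(config)) {
    pick <- function(f) {
      p <- file.path(config, f)
      if (file.exists(p)) p else NULL
    }
    config <- run_config(edges = pick("links.tsv"), panel = pick("panel.csv"),
                         phospho = pick("phospho.csv"),
                         fasta = pick("seqs.fasta"),
                         orthologs = pick("orthologs.tsv"),
                         catalog = pick("catalog.csv"),
                         gmt = pick("annotations.gmt"))
  }
  stopifnot(inherits(config, "run_config"))
  bundle <- list()
  counts <- list()
  notices <- character()
  skip <- function(stage, why) {
    notices <<- c(notices, paste0(stage, " skipped: ", why))
    message(stage, " skipped: ", why)
  }

  panel <- NULL
  if (!is.null(config$panel)) {
    panel <- read_seed_panel(config$panel)
  }

  if (!is.null(config$edges) && !is.null(panel)) {
    network <- read_association_table(config$edges)
    inter <- build_interactome(network, panel,
                               min_confidence = config$min_confidence)
    ov <- overlap_table(inter)
    pw <- pairwise_intersections(inter)
    sp <- syndrome_partition(inter, panel)
    analysis_net <- restrict_network(network,
                                     union(inter$unique_union, inter$seeds))
    hr <- hub_report(analysis_net, multiplier = config$hub_multiplier,
                     min_confidence = config$min_confidence)
    bundle$network <- network
    bundle$interactome <- inter
    bundle$overlap <- ov
    bundle$pairwise <- pw
    bundle$syndromes <- sp
    bundle$hubs <- hr
    counts$interactome <- list(
      seeds = length(inter$seeds),
      total_with_duplicates = inter$total_with_duplicates,
      unique_union = length(inter$unique_union),
      pairs = nrow(pw$pairs),
      hubs = nrow(hr$hubs)
    )
  } else {
    skip("interactome stage", "needs edges and panel inputs")
  }

  if (!is.null(config$phospho)) {
    records <- read_phospho_table(config$phospho)
    seqs <- if (!is.null(config$fasta)) read_fasta(config$fasta) else NULL
    orth <- if (!is.null(config$orthologs)) {
      read_tsv(config$orthologs)
    } else {
      NULL
    }
    records <- map_records_to_human(records, seqs, orth)
    if (!is.null(bundle$interactome)) {
      cl <- crosslink_interactome(records, bundle$interactome)
      records <- cl$records
      counts$crosslink <- list(records = nrow(records),
                               phosphoproteins = cl$n_phosphoproteins)
    }
    records <- apply_threshold(records, config$fc_threshold)
    dm <- build_matrix(records, threshold = config$fc_threshold)
    bundle$phospho_records <- records
    bundle$matrix <- dm
    bundle$summary_by_syndrome <- summarize_by_syndrome(records,
                                                        config$fc_threshold)
    if (all(config$cluster_cols %in% colnames(dm$log2fc))) {
      bundle$clusters <- assign_clusters(dm, config$cluster_cols)
    }
    counts$phospho <- list(
      records = nrow(records),
      mapped = sum(records$mapped),
      unmapped = sum(!records$mapped),
      matrix_rows = nrow(dm$log2fc),
      value_cells = sum(!is.na(dm$log2fc)),
      unchanged_cells = sum(dm$unchanged)
    )
  } else {
    skip("phospho stage", "needs the phosphosite table")
  }

  if (!is.null(config$catalog) && !is.null(panel)) {
    catalog <- read_phospho_catalog(config$catalog)
    census <- build_census(catalog, panel)
    bundle$census <- census
    bundle$bubble <- bubble_table(census, panel)
    counts$census <- list(proteins = nrow(census$entries),
                          sites = census$totals$n_sites_total)
  } else {
    skip("census stage", "needs catalog and panel inputs")
  }

  if (!is.null(config$gmt) && !is.null(bundle$phospho_records)) {
    sets <- read_gmt(config$gmt)
    rec <- bundle$phospho_records
    dys <- rec$status %in% c("up", "down")
    query <- unique(rec$human_accession[dys & !is.na(rec$human_accession)])
    background <- unique(unlist(lapply(sets, `[[`, "members"),
                                use.names = FALSE))
    query <- intersect(query, background)
    if (length(query) == 0) {
      skip("enrichment stage", "no dysregulated proteins in the background")
    } else {
      enr <- overrepresentation(query, sets, background,
                                fdr_cutoff = config$fdr_cutoff)
      bundle$enrichment <- enr
      counts$enrichment <- list(terms = nrow(enr),
                                significant = sum(enr$significant))
    }
  } else {
    skip("enrichment stage", "needs annotations and phospho records")
  }

  bundle$summary <- list(
    parameters = list(min_confidence = config$min_confidence,
                      hub_multiplier = config$hub_multiplier,
                      fc_threshold = config$fc_threshold,
                      fdr_cutoff = config$fdr_cutoff),
    counts = counts,
    notices = notices
  )

  if (!is.null(config$out_dir)) {
    write_report(bundle, config$out_dir)
  }
  invisible(bundle)
}

#' Write a report bundle to disk
#'
#' Emits every computed table as TSV plus a `summary.json`.
#'
#' @param bundle A report bundle from [run_all()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$overlap)) {
    write_tsv(bundle$overlap, file.path(dir, "overlap.tsv"))
    write_tsv(bundle$pairwise$pairs, file.path(dir, "pairs.tsv"))
    hist_df <- data.frame(bin = names(bundle$pairwise$histogram),
                          n_pairs = as.integer(bundle$pairwise$histogram),
                          stringsAsFactors = FALSE)
    write_tsv(hist_df, file.path(dir, "pair_histogram.tsv"))
    write_tsv(bundle$hubs$hubs, file.path(dir, "hubs.tsv"))
    write_tsv(bundle$syndromes, file.path(dir, "syndrome_partition.tsv"))
  }
  if (!is.null(bundle$matrix)) {
    write_tsv(as.data.frame(bundle$matrix), file.path(dir, "matrix.tsv"))
    write_tsv(bundle$summary_by_syndrome,
              file.path(dir, "syndrome_summary.tsv"))
    if (!is.null(bundle$clusters)) {
      write_tsv(bundle$clusters, file.path(dir, "clusters.tsv"))
    }
  }
  if (!is.null(bundle$census)) {
    write_tsv(bundle$census$entries, file.path(dir, "census.tsv"))
    write_tsv(bundle$bubble, file.path(dir, "bubble.tsv"))
  }
  if (!is.null(bundle$enrichment)) {
    write_tsv(bundle$enrichment, file.path(dir, "enrichment.tsv"))
  }
  write_json(bundle$summary, file.path(dir, "summary.json"))
  invisible(dir)
}
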