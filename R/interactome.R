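#' Build a seed-panel interactome
#'
#' For every seed protein in the panel, collects its direct association
#' partners from the network at or above a confidence cutoff, optionally
#' augmented with partners from an extra per-seed source (e.g. a curated
#' interaction export). The seed itself is never a member of its own
#' neighbor set; another seed appearing as a neighbor is kept. The total
#' with duplicates counts every (seed, partner) occurrence, while the
#' unique union deduplicates partners by accession across all seeds.
#'
#' @param network An [assoc_network()].
#' @param panel A `seed_panel` (see [read_seed_panel()]).
#' @param min_confidence Minimum edge confidence for a partner to count
#'   (default 0.700, the conventional high-confidence cutoff).
#' @param extra_sources Optional named list mapping seed accession to a
#'   character vector of additional partner accessions.
#' @return An `interactome`: a list with `neighbor_sets` (named list,
#'   seed accession to sorted partner accessions), `total_with_duplicates`,
#'   `unique_union` (sorted accessions), `seeds`, and `panel`.
#' @export
build_interactome <- function(network, panel, min_confidence = 0.700,
                              extra_sources = NULL) {
  stopifnot(inherits(network, "assoc_network"),
            inherits(panel, "seed_panel"),
            min_confidence >= 0, min_confidence <= 1)
  seeds <- panel$accession
  ed <- network$edges[network$edges$confidence >= min_confidence, , drop = FALSE]
  neighbor_sets <- vector("list", length(seeds))
  names(neighbor_sets) <- seeds
  n_absent <- 0L
  for (s in seeds) {
    nb <- c(ed$b[ed$a == s], ed$a[ed$b == s])
    if (!is.null(extra_sources) && !is.null(extra_sources[[s]])) {
      nb <- c(nb, extra_sources[[s]])
    } else if (length(nb) == 0 && !s %in% network$nodes) {
      n_absent <- n_absent + 1L
    }
    neighbor_sets[[s]] <- sort(unique(setdiff(nb, s)))
  }
  if (n_absent > 0) {
    warning(n_absent, " seed(s) absent from the network and from extra ",
            "sources: empty neighbor sets", call. = FALSE)
  }
  structure(
    list(neighbor_sets = neighbor_sets,
         total_with_duplicates = sum(lengths(neighbor_sets)),
         unique_union = sort(unique(unlist(neighbor_sets, use.names = FALSE))),
         seeds = seeds,
         panel = panel),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("Interactome:", length(x$seeds), "seeds,",
      x$total_with_duplicates, "partners with duplicates,",
      length(x$unique_union), "unique partners\n")
  invisible(x)
}

#' Per-seed interactome overlap table
#'
#' For each seed, counts its direct partners (N), the partners that also
#' appear in at least one other seed's neighbor set, and the percentage of
#' overlap (100 * shared / N). Seeds without partners report a missing
#' percentage. The unweighted mean percentage over seeds with partners is
#' attached as attribute `mean_percent`.
#'
#' @param interactome An `interactome` from [build_interactome()].
#' @return Data frame with columns `seed`, `gene_symbol`, `n_partners`,
#'   `n_shared`, `percent`, and attribute `mean_percent`.
#' @export
overlap_table <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  ns <- interactome$neighbor_sets
  if (length(ns) < 2) {
    stop("overlap is undefined for fewer than 2 seeds", call. = FALSE)
  }
  seeds <- names(ns)
  rows <- lapply(seq_along(seeds), function(i) {
    others <- unique(unlist(ns[-i], use.names = FALSE))
    n <- length(ns[[i]])
    shared <- length(intersect(ns[[i]], others))
    data.frame(seed = seeds[i],
               n_partners = n,
               n_shared = shared,
               percent = if (n > 0) 100 * shared / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sym <- interactome$panel$gene_symbol[match(out$seed,
                                             interactome$panel$accession)]
  out <- data.frame(seed = out$seed, gene_symbol = sym,
                    out[, c("n_partners", "n_shared", "percent")],
                    stringsAsFactors = FALSE)
  attr(out, "mean_percent") <- mean(out$percent, na.rm = TRUE)
  out
}

#' Pairwise interactome intersections
#'
#' Computes the size of the neighbor-set intersection for every unordered
#' seed pair (k seeds give k(k-1)/2 pairs), the histogram of intersection
#' sizes over the bins 0, 1-5, 6-10, >10, and the pairs ranked by shared
#' count (ties broken lexicographically by accession pair).
#'
#' @param interactome An `interactome`.
#' @return A list with `pairs` (data frame `a`, `b`, `n_shared`, sorted by
#'   decreasing `n_shared`), `matrix` (symmetric intersection-size matrix),
#'   and `histogram` (named counts for bins `0`, `1-5`, `6-10`, `>10`).
#' @export
pairwise_intersections <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  ns <- interactome$neighbor_sets
  k <- length(ns)
  if (k < 2) stop("need at least 2 seeds", call. = FALSE)
  seeds <- names(ns)
  m <- matrix(0L, k, k, dimnames = list(seeds, seeds))
  a <- character(); b <- character(); shared <- integer()
  idx <- 0L
  n_pairs <- k * (k - 1L) / 2L
  a <- vector("character", n_pairs)
  b <- vector("character", n_pairs)
  shared <- vector("integer", n_pairs)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- length(intersect(ns[[i]], ns[[j]]))
      m[i, j] <- s
      m[j, i] <- s
      idx <- idx + 1L
      a[idx] <- seeds[i]; b[idx] <- seeds[j]; shared[idx] <- s
    }
  }
  pairs <- data.frame(a = a, b = b, n_shared = shared,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$n_shared, pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  hist <- c(`0` = sum(shared == 0),
            `1-5` = sum(shared >= 1 & shared <= 5),
            `6-10` = sum(shared >= 6 & shared <= 10),
            `>10` = sum(shared > 10))
  list(pairs = pairs, matrix = m, histogram = hist)
}

#' Partition the interactome by syndrome
#'
#' For each syndrome, forms the protein set given by the union of the
#' neighbor sets of that syndrome's seeds plus the seeds themselves, then
#' counts how many of those proteins are shared with the union of all the
#' other syndromes' sets. A protein may belong to several syndrome sets.
#' Percentages are reported on two bases: the grand total of the
#' per-syndrome listing (set sizes summed, counting proteins once per
#' syndrome) and the number of unique proteins across all sets.
#'
#' @param interactome An `interactome`.
#' @param panel Seed panel carrying the syndrome assignments; defaults to
#'   the panel stored in the interactome.
#' @return Data frame with columns `syndrome`, `n_proteins`, `n_shared`,
#'   `pct_of_listing`, `pct_of_unique`; attributes `grand_total_listing`
#'   and `n_unique`.
#' @export
syndrome_partition <- function(interactome, panel = interactome$panel) {
  stopifnot(inherits(interactome, "interactome"))
  sets <- list()
  for (i in seq_len(nrow(panel))) {
    acc <- panel$accession[i]
    if (!acc %in% names(interactome$neighbor_sets)) next
    members <- c(acc, interactome$neighbor_sets[[acc]])
    for (syn in panel$syndromes[[i]]) {
      sets[[syn]] <- union(sets[[syn]], members)
    }
  }
  syn_names <- sort(names(sets))
  listing_total <- sum(lengths(sets))
  n_unique <- length(unique(unlist(sets, use.names = FALSE)))
  rows <- lapply(syn_names, function(s) {
    others <- unique(unlist(sets[setdiff(syn_names, s)], use.names = FALSE))
    shared <- length(intersect(sets[[s]], others))
    data.frame(syndrome = s,
               n_proteins = length(sets[[s]]),
               n_shared = shared,
               pct_of_listing = 100 * shared / listing_total,
               pct_of_unique = 100 * shared / n_unique,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sets") <- sets
  attr(out, "grand_total_listing") <- listing_total
  attr(out, "n_unique") <- n_unique
  out
}

#' Degree-based hub detection
#'
#' Flags nodes whose degree strictly exceeds a multiple of the network's
#' mean degree. The mean degree is 2E/V over the whole analyzed network,
#' including degree-0 nodes; restrict the network first (e.g. to the
#' interactome union plus seeds) with [restrict_network()] if hubs should
#' be sought within a subnetwork.
#'
#' @param network An [assoc_network()].
#' @param multiplier Hub cutoff as a multiple of the mean degree
#'   (default 4).
#' @param min_confidence Count only edges at or above this confidence.
#' @return A `hub_report`: list with `mean_degree`, `multiplier`, `cutoff`,
#'   and `hubs` (data frame `accession`, `degree`, sorted by decreasing
#'   degree, ties broken by accession).
#' @export
hub_report <- function(network, multiplier = 4, min_confidence = 0) {
  stopifnot(inherits(network, "assoc_network"), multiplier > 0)
  if (length(network$nodes) == 0) {
    stop("cannot compute hubs on an empty network", call. = FALSE)
  }
  deg <- network_degrees(network, min_confidence)
  n_edges <- sum(deg) / 2
  mean_degree <- 2 * n_edges / length(deg)
  cutoff <- multiplier * mean_degree
  hub <- deg[deg > cutoff]
  hubs <- data.frame(accession = names(hub), degree = as.integer(hub),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$accession), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(mean_degree = mean_degree, multiplier = multiplier,
                 cutoff = cutoff, hubs = hubs),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub report: mean degree %.2f, cutoff %.2f (x%g), %d hub(s)\n",
              x$mean_degree, x$cutoff, x$multiplier, nrow(x$hubs)))
  if (nrow(x$hubs) > 0) {
    print(utils::head(x$hubs, 12), row.names = FALSE)
  }
  invisible(x)
}
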