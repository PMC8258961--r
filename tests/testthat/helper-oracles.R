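# Naive re-implementations used as independent oracles, plus tiny
# fixture builders. Everything here is deliberately brute-force.

naive_overlap <- function(sets) {
  out <- data.frame(seed = names(sets), n_partners = NA_integer_,
                    n_shared = NA_integer_, percent = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    others <- character()
    for (j in seq_along(sets)) {
      if (j != i) others <- c(others, sets[[j]])
    }
    others <- unique(others)
    shared <- 0L
    for (x in sets[[i]]) {
      if (x %in% others) shared <- shared + 1L
    }
    out$n_partners[i] <- length(sets[[i]])
    out$n_shared[i] <- shared
    out$percent[i] <- if (length(sets[[i]]) > 0) {
      100 * shared / length(sets[[i]])
    } else {
      NA_real_
    }
  }
  out
}

naive_pair_sizes <- function(sets) {
  k <- length(sets)
  sizes <- integer()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      n <- 0L
      for (x in sets[[i]]) if (x %in% sets[[j]]) n <- n + 1L
      sizes <- c(sizes, n)
    }
  }
  sizes
}

naive_degrees <- function(edges, nodes) {
  deg <- stats::setNames(integer(length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    deg[edges$a[r]] <- deg[edges$a[r]] + 1L
    deg[edges$b[r]] <- deg[edges$b[r]] + 1L
  }
  deg
}

# upper-tail hypergeometric by direct summation of choose() products
naive_hyper_tail <- function(k, K, N, n) {
  tot <- 0
  for (i in k:min(n, K)) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}

random_edge_table <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  a <- character(); b <- character()
  while (length(a) < n_edges) {
    p <- sample(nodes, 2)
    key <- paste(min(p), max(p))
    if (!key %in% paste(pmin(a, b), pmax(a, b))) {
      a <- c(a, p[1]); b <- c(b, p[2])
    }
  }
  data.frame(a = a, b = b,
             confidence = round(runif(n_edges, 0.1, 1), 3),
             stringsAsFactors = FALSE)
}

# build a seed_panel object directly from a named list of syndrome vectors
make_panel <- function(syndromes_by_accession) {
  acc <- names(syndromes_by_accession)
  panel <- data.frame(accession = acc, gene_symbol = acc,
                      stringsAsFactors = FALSE)
  panel$syndromes <- unname(syndromes_by_accession)
  structure(panel, aliases = list(), class = c("seed_panel", "data.frame"))
}

# build an interactome object directly from neighbor sets
make_interactome <- function(sets, panel = NULL) {
  if (is.null(panel)) {
    panel <- make_panel(stats::setNames(rep(list("NS"), length(sets)),
                                        names(sets)))
  }
  structure(
    list(neighbor_sets = lapply(sets, sort),
         total_with_duplicates = sum(lengths(sets)),
         unique_union = sort(unique(unlist(sets, use.names = FALSE))),
         seeds = names(sets),
         panel = panel),
    class = "interactome"
  )
}

# minimal phosphosite record table in post-reader shape
make_records <- function(accession, syndrome, fold_change = NA,
                         direction = NA_character_, residue = "Y",
                         position = 10L, organism = "human",
                         assay = "MS", study_ref = "s1") {
  n <- length(accession)
  df <- data.frame(
    accession = accession, gene_symbol = accession,
    organism = rep_len(organism, n), residue = rep_len(residue, n),
    position = rep_len(as.integer(position), n),
    fold_change = as.numeric(rep_len(fold_change, n)),
    direction = rep_len(direction, n), assay = rep_len(assay, n),
    syndrome = rep_len(syndrome, n), study_ref = rep_len(study_ref, n),
    stringsAsFactors = FALSE
  )
  df$quantitative <- !is.na(df$fold_change)
  assign_replicate_tags(df)
}
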