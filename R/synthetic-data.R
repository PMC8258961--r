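# Run code under a fixed RNG seed without touching global RNG state.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "W", "V", "S", "T", "Y")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the statistical structure of a RASopathy seed-panel
#' study: 27 seed proteins over a sparse association graph of ~500
#' proteins with roughly 40 high-confidence partners per seed, a
#' moderate shared-partner fraction, a few planted high-degree hubs,
#' and a phosphoproteome plan with dozens of up- and a smaller number of
#' downregulated sites in NS and NSML (plus a few in NF1), measured in
#' human, mouse and zebrafish models with sequence divergence and indels.
#'
#' @param rng_seed Integer seed driving all randomness.
#' @param n_seeds Number of seed proteins.
#' @param n_pool Size of the non-seed protein pool.
#' @param n_shared_pool Size of the communal pool from which overlapping
#'   neighbors are drawn (includes the planted hubs).
#' @param neighbors_per_seed Integer range (length 2) of direct partners
#'   per seed.
#' @param pairwise_overlap Expected fraction of each seed's neighbors
#'   drawn from the communal pool (0 disables sharing entirely:
#'   neighbor sets are then drawn mutually disjoint).
#' @param planted_hubs Number of planted hub nodes.
#' @param hub_degree Target degree of each planted hub (within the
#'   high-confidence subnetwork induced on the interactome).
#' @param background_edges Number of random high-confidence edges among
#'   non-seed interactome members (sets the mean degree the hub cutoff
#'   is measured against).
#' @param decoy_edges Number of sub-cutoff (confidence < 0.7) edges
#'   added anywhere in the graph to exercise confidence filtering.
#' @param phospho_plan Named list: syndrome token to a list with counts
#'   `n_up`, `n_down`, `n_unchanged`, `n_qual_up`, `n_qual_down`,
#'   `n_qual_undefined`, `n_dup` and fold-change ranges `fc_up`
#'   (within (1.5, Inf)) and `fc_down` (within (0, 1/1.5)).
#' @param cross_plan Cross-syndrome structure between `cross_cols`:
#'   `n_both_up` sites upregulated in both, `n_both_down` downregulated
#'   in both, `n_discordant` down in the first / up in the second, and
#'   `n_up_first_unch_second` up in the first with an explicit
#'   reported-unchanged measurement in the second.
#' @param cross_cols The two syndromes the cross plan applies to.
#' @param organisms Data frame with columns `organism`, `weight`
#'   (sampling weight), `sub_rate` (per-residue substitution rate) and
#'   `n_indels` (indel events per derived ortholog sequence).
#' @param seq_length Integer range of simulated protein lengths.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_seeds = 27L,
                       n_pool = 500L,
                       n_shared_pool = 100L,
                       neighbors_per_seed = c(35L, 45L),
                       pairwise_overlap = 0.3,
                       planted_hubs = 3L,
                       hub_degree = 80L,
                       background_edges = 1800L,
                       decoy_edges = 300L,
                       phospho_plan = list(
                         NS = list(n_up = 40, n_down = 13, n_unchanged = 4,
                                   n_qual_up = 3, n_qual_down = 1,
                                   n_qual_undefined = 1, n_dup = 2,
                                   fc_up = c(1.6, 8), fc_down = c(0.02, 0.6)),
                         NSML = list(n_up = 55, n_down = 20, n_unchanged = 4,
                                     n_qual_up = 3, n_qual_down = 2,
                                     n_qual_undefined = 0, n_dup = 1,
                                     fc_up = c(1.6, 7), fc_down = c(0.02, 0.6)),
                         NF1 = list(n_up = 6, n_down = 2, n_unchanged = 0,
                                    n_qual_up = 2, n_qual_down = 1,
                                    n_qual_undefined = 0, n_dup = 0,
                                    fc_up = c(1.6, 5), fc_down = c(0.1, 0.6))
                       ),
                       cross_plan = list(n_both_up = 2, n_both_down = 2,
                                         n_discordant = 1,
                                         n_up_first_unch_second = 1),
                       cross_cols = c("NS", "NSML"),
                       organisms = data.frame(
                         organism = c("human", "mouse", "zebrafish"),
                         weight = c(0.4, 0.3, 0.3),
                         sub_rate = c(0, 0.08, 0.15),
                         n_indels = c(0L, 1L, 2L),
                         stringsAsFactors = FALSE
                       ),
                       seq_length = c(250L, 400L)) {
  stopifnot(length(rng_seed) == 1, is.finite(rng_seed),
            n_seeds >= 1, n_pool >= 1, n_shared_pool <= n_pool,
            length(neighbors_per_seed) == 2,
            neighbors_per_seed[1] <= neighbors_per_seed[2],
            pairwise_overlap >= 0, pairwise_overlap <= 1,
            planted_hubs >= 0, planted_hubs <= n_shared_pool,
            hub_degree >= 1,
            background_edges >= 0, decoy_edges >= 0,
            all(organisms$weight >= 0), sum(organisms$weight) > 0,
            all(organisms$sub_rate >= 0 & organisms$sub_rate < 1),
            all(organisms$n_indels >= 0),
            "human" %in% organisms$organism,
            length(seq_length) == 2, seq_length[1] >= 50)
  for (s in names(phospho_plan)) {
    p <- phospho_plan[[s]]
    counts <- unlist(p[c("n_up", "n_down", "n_unchanged", "n_qual_up",
                         "n_qual_down", "n_qual_undefined", "n_dup")])
    if (any(counts < 0)) stop("phospho plan counts must be >= 0", call. = FALSE)
    if (p$n_up > 0 && p$fc_up[1] <= 1.5) {
      stop("fc_up range must lie strictly above 1.5", call. = FALSE)
    }
    if (p$n_down > 0 && p$fc_down[2] >= 1 / 1.5) {
      stop("fc_down range must lie strictly below 1/1.5", call. = FALSE)
    }
    if (p$n_dup > p$n_up) {
      stop("n_dup cannot exceed n_up for syndrome ", s, call. = FALSE)
    }
  }
  structure(
    list(rng_seed = as.integer(rng_seed), n_seeds = as.integer(n_seeds),
         n_pool = as.integer(n_pool),
         n_shared_pool = as.integer(n_shared_pool),
         neighbors_per_seed = as.integer(neighbors_per_seed),
         pairwise_overlap = pairwise_overlap,
         planted_hubs = as.integer(planted_hubs),
         hub_degree = as.integer(hub_degree),
         background_edges = as.integer(background_edges),
         decoy_edges = as.integer(decoy_edges),
         phospho_plan = phospho_plan, cross_plan = cross_plan,
         cross_cols = cross_cols, organisms = organisms,
         seq_length = as.integer(seq_length)),
    class = "sim_config"
  )
}

# sample() without its length-1 surprise
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a synthetic association network with known structure
#'
#' Builds a seed panel and an association network in which every
#' analysis-level quantity is known by construction: each seed's true
#' neighbor set (all seed-partner edges at confidence >= 0.7), the
#' pairwise neighbor-set intersections, and the hub list of the
#' high-confidence subnetwork induced on the interactome (union of
#' neighbor sets plus seeds). Sharing between neighbor sets comes only
#' from a communal pool whose size and sampling fraction are
#' configurable; planted hubs are forced into the interactome and
#' topped up with high-confidence edges to their target degree. Decoy
#' edges below the 0.7 cutoff are added to exercise confidence
#' filtering. All confidences are rounded to 3 decimals so that files
#' round-trip exactly through the permille dialect.
#'
#' @param cfg A [sim_config()].
#' @return A list with `network` (an [assoc_network()]), `panel` (a
#'   `seed_panel`), and `truth` (list: `neighbor_sets`,
#'   `total_with_duplicates`, `unique_union`, `pairwise` data frame,
#'   `histogram`, `hubs` data frame, `mean_degree`, `cutoff`,
#'   `planted_hubs`).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng_seed(cfg$rng_seed, {
    seeds <- sprintf("SEED%02d", seq_len(cfg$n_seeds))
    hubs <- if (cfg$planted_hubs > 0) {
      sprintf("HUB%02d", seq_len(cfg$planted_hubs))
    } else {
      character()
    }
    n_prot <- cfg$n_pool - length(hubs)
    pool <- sprintf("PROT%03d", seq_len(n_prot))
    shared_pool <- c(hubs, utils::head(pool, cfg$n_shared_pool - length(hubs)))
    private_pool <- setdiff(pool, shared_pool)

    n_i <- sample_from(seq(cfg$neighbors_per_seed[1],
                           cfg$neighbors_per_seed[2]),
                       cfg$n_seeds, replace = TRUE)
    neighbor_sets <- vector("list", cfg$n_seeds)
    names(neighbor_sets) <- seeds
    if (cfg$pairwise_overlap == 0) {
      if (sum(n_i) > length(private_pool)) {
        stop("disjoint neighbor sets need a pool of at least ", sum(n_i),
             " private proteins", call. = FALSE)
      }
      picks <- sample_from(private_pool, sum(n_i))
      stops <- cumsum(n_i)
      starts <- c(1L, utils::head(stops, -1L) + 1L)
      for (i in seq_len(cfg$n_seeds)) {
        neighbor_sets[[i]] <- picks[starts[i]:stops[i]]
      }
    } else {
      for (i in seq_len(cfg$n_seeds)) {
        k_shared <- min(round(cfg$pairwise_overlap * n_i[i]),
                        length(shared_pool))
        k_priv <- n_i[i] - k_shared
        neighbor_sets[[i]] <- c(sample_from(shared_pool, k_shared),
                                sample_from(private_pool, k_priv))
      }
    }
    # force every planted hub into at least two neighbor sets
    if (length(hubs) > 0 && cfg$n_seeds >= 1) {
      for (j in seq_along(hubs)) {
        carriers <- ((j - 1L) * 2L + c(0L, 1L)) %% cfg$n_seeds + 1L
        for (i in unique(carriers)) {
          neighbor_sets[[i]] <- union(neighbor_sets[[i]], hubs[j])
        }
      }
    }
    neighbor_sets <- lapply(neighbor_sets, sort)

    conf_hi <- function(n) round(stats::runif(n, 0.700, 0.999), 3)
    ed_a <- character(); ed_b <- character(); ed_c <- numeric()
    for (i in seq_len(cfg$n_seeds)) {
      nb <- neighbor_sets[[i]]
      ed_a <- c(ed_a, rep(seeds[i], length(nb)))
      ed_b <- c(ed_b, nb)
      ed_c <- c(ed_c, conf_hi(length(nb)))
    }
    union_set <- sort(unique(unlist(neighbor_sets, use.names = FALSE)))
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    existing <- unique(pair_key(ed_a, ed_b))

    # background edges among non-seed interactome members lift the mean
    # degree the hub cutoff is measured against without inflating seed
    # degrees
    if (cfg$background_edges > 0 && length(union_set) >= 2) {
      added <- 0L
      guard <- 0L
      while (added < cfg$background_edges && guard < cfg$background_edges * 20) {
        guard <- guard + 1L
        p <- sample_from(union_set, 2L)
        key <- pair_key(p[1], p[2])
        if (key %in% existing) next
        existing <- c(existing, key)
        ed_a <- c(ed_a, p[1]); ed_b <- c(ed_b, p[2])
        ed_c <- c(ed_c, conf_hi(1))
        added <- added + 1L
      }
    }
    # top planted hubs up to their target degree
    analysis_nodes <- union(union_set, seeds)
    if (length(hubs) > 0) {
      if (cfg$hub_degree >= length(analysis_nodes)) {
        stop("hub target degree ", cfg$hub_degree,
             " is infeasible for an interactome of ",
             length(analysis_nodes), " nodes", call. = FALSE)
      }
      for (h in hubs) {
        deg_h <- sum((ed_a == h | ed_b == h))
        partners <- setdiff(union_set, c(h, seeds))
        partners <- partners[!pair_key(h, partners) %in% existing]
        need <- cfg$hub_degree - deg_h
        if (need > length(partners)) {
          stop("cannot reach hub target degree for ", h, call. = FALSE)
        }
        if (need > 0) {
          add <- sample_from(partners, need)
          existing <- c(existing, pair_key(h, add))
          ed_a <- c(ed_a, rep(h, need)); ed_b <- c(ed_b, add)
          ed_c <- c(ed_c, conf_hi(need))
        }
      }
    }
    # sub-cutoff decoys anywhere in the graph
    all_nodes <- c(seeds, hubs, pool)
    if (cfg$decoy_edges > 0) {
      added <- 0L
      guard <- 0L
      while (added < cfg$decoy_edges && guard < cfg$decoy_edges * 20) {
        guard <- guard + 1L
        p <- sample_from(all_nodes, 2L)
        key <- pair_key(p[1], p[2])
        if (key %in% existing) next
        existing <- c(existing, key)
        ed_a <- c(ed_a, p[1]); ed_b <- c(ed_b, p[2])
        ed_c <- c(ed_c, round(stats::runif(1, 0.150, 0.699), 3))
        added <- added + 1L
      }
    }
    network <- assoc_network(
      data.frame(a = ed_a, b = ed_b, confidence = ed_c,
                 stringsAsFactors = FALSE),
      nodes = all_nodes
    )

    # seed panel: cycle syndrome assignments so that several syndromes
    # exist and some seeds carry two
    syn_cycle <- list("NS", "NSML", c("NS", "NSML"), "NF1")
    panel <- data.frame(accession = seeds, gene_symbol = seeds,
                        stringsAsFactors = FALSE)
    panel$syndromes <- lapply(seq_len(cfg$n_seeds), function(i) {
      syn_cycle[[(i - 1L) %% length(syn_cycle) + 1L]]
    })
    panel <- structure(panel, aliases = list(),
                       class = c("seed_panel", "data.frame"))

    # ground truth by naive enumeration on the construction-time sets
    k <- cfg$n_seeds
    pa <- character(); pb <- character(); ps <- integer()
    if (k >= 2) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          pa <- c(pa, seeds[i]); pb <- c(pb, seeds[j])
          ps <- c(ps, length(intersect(neighbor_sets[[i]],
                                       neighbor_sets[[j]])))
        }
      }
    }
    pairwise <- data.frame(a = pa, b = pb, n_shared = ps,
                           stringsAsFactors = FALSE)
    histogram <- c(`0` = sum(ps == 0), `1-5` = sum(ps >= 1 & ps <= 5),
                   `6-10` = sum(ps >= 6 & ps <= 10), `>10` = sum(ps > 10))
    hi <- ed_c >= 0.700 & ed_a %in% analysis_nodes & ed_b %in% analysis_nodes
    deg <- table(factor(c(ed_a[hi], ed_b[hi]), levels = sort(analysis_nodes)))
    deg <- stats::setNames(as.integer(deg), names(deg))
    mean_degree <- sum(deg) / length(deg)
    cutoff <- 4 * mean_degree
    hub_deg <- deg[deg > cutoff]
    truth_hubs <- data.frame(accession = names(hub_deg),
                             degree = as.integer(hub_deg),
                             stringsAsFactors = FALSE)
    truth_hubs <- truth_hubs[order(-truth_hubs$degree, truth_hubs$accession),
                             , drop = FALSE]
    rownames(truth_hubs) <- NULL
    if (!all(hubs %in% truth_hubs$accession)) {
      stop("planted hub(s) did not exceed 4x the realized mean degree; ",
           "raise hub_degree or lower background_edges", call. = FALSE)
    }
    truth <- list(
      neighbor_sets = neighbor_sets,
      total_with_duplicates = sum(lengths(neighbor_sets)),
      unique_union = union_set,
      pairwise = pairwise,
      histogram = histogram,
      hubs = truth_hubs,
      mean_degree = mean_degree,
      cutoff = cutoff,
      planted_hubs = hubs
    )
    list(network = network, panel = panel, truth = truth)
  })
}

# Derive a model-organism ortholog sequence from a human one: random
# substitutions (never at planted sites, replacements never S/T/Y) and
# short indels placed away from every planted site. Returns the derived
# sequence and the source-coordinate positions of the planted sites.
mutate_sequence <- function(human_seq, site_positions, sub_rate, n_indels) {
  chars <- strsplit(human_seq, "")[[1]]
  sites <- as.integer(site_positions)
  cand <- setdiff(seq_along(chars), sites)
  n_sub <- round(sub_rate * length(cand))
  if (n_sub > 0) {
    at <- sample_from(cand, n_sub)
    repl_pool <- setdiff(AA20, c("S", "T", "Y"))
    chars[at] <- vapply(chars[at], function(orig) {
      sample_from(setdiff(repl_pool, orig), 1L)
    }, "")
  }
  if (n_indels > 0) {
    for (j in seq_len(n_indels)) {
      len_i <- sample_from(1:3, 1L)
      ok <- function(p) {
        span <- p:(p + len_i - 1L)
        p > 5 && (p + len_i - 1L) < (length(chars) - 5L) &&
          all(vapply(span, function(q) all(abs(q - sites) > 5L), TRUE))
      }
      cand_pos <- which(vapply(seq_along(chars), ok, TRUE))
      if (length(cand_pos) == 0) next
      p <- sample_from(cand_pos, 1L)
      if (stats::runif(1) < 0.5) {
        ins <- sample_from(setdiff(AA20, c("S", "T", "Y")), len_i,
                           replace = TRUE)
        chars <- append(chars, ins, after = p - 1L)
        sites <- ifelse(sites >= p, sites + len_i, sites)
      } else {
        chars <- chars[-(p:(p + len_i - 1L))]
        sites <- ifelse(sites > p + len_i - 1L, sites - len_i, sites)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), site_positions = sites)
}

#' Generate a synthetic phosphosite table with known dysregulation
#'
#' Plants, per syndrome, a configured number of up-, down- and
#' unchanged-measured phosphosites (quantitative MS records), qualitative
#' immunoblot direction calls, replicate re-measurements from a second
#' study, and cross-syndrome structure (sites dysregulated in both
#' target syndromes, concordantly or discordantly). Non-human records
#' are emitted in source-organism coordinates on ortholog sequences
#' derived from the human ones by substitutions and indels, so that
#' alignment-based mapping must recover the planted human site. The
#' truth record stores every planted human coordinate and the expected
#' downstream tallies.
#'
#' @param cfg A [sim_config()].
#' @param proteins Optional accession pool to draw phosphoproteins from
#'   (e.g. interactome members so that cross-linking retains all
#'   records); synthetic accessions are invented when `NULL`.
#' @return A list with `records` (a table in the on-disk phosphosite CSV
#'   shape), `sequences` (named character vector: human and derived
#'   ortholog sequences), `orthologs` (source-to-human accession table),
#'   and `truth` (per-syndrome site/record counts, expected matrix cell
#'   and cluster counts, per-record planted human coordinates, distinct
#'   phosphoprotein count).
#' @export
generate_phospho <- function(cfg, proteins = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng_seed(cfg$rng_seed + 1L, {
    plan <- cfg$phospho_plan
    cross <- cfg$cross_plan
    ccols <- cfg$cross_cols

    # --- phase 1: plan distinct sites and the records on them ---------
    site_protein <- character()
    new_sites <- function(n, what) {
      if (n == 0) return(integer(0))
      ids <- length(site_protein) + seq_len(n)
      site_protein[ids] <<- NA_character_
      ids
    }
    rec <- list()
    add_rec <- function(site_id, syndrome, kind, fc = NA_real_,
                        direction = NA_character_, assay = "MS",
                        study_ref, organism = NA_character_) {
      rec[[length(rec) + 1L]] <<- list(site_id = site_id,
                                       syndrome = syndrome, kind = kind,
                                       fc = fc, direction = direction,
                                       assay = assay, study_ref = study_ref,
                                       organism = organism)
    }
    rfc <- function(range) round(stats::runif(1, range[1], range[2]), 3)

    per_syn_sites <- list()
    for (s in names(plan)) {
      p <- plan[[s]]
      up_ids <- new_sites(p$n_up)
      for (id in up_ids) {
        add_rec(id, s, "up", fc = rfc(p$fc_up), study_ref = paste0(s, "_MS1"))
      }
      for (id in new_sites(p$n_down)) {
        add_rec(id, s, "down", fc = rfc(p$fc_down),
                study_ref = paste0(s, "_MS1"))
      }
      for (id in new_sites(p$n_unchanged)) {
        add_rec(id, s, "unchanged", fc = round(stats::runif(1, 0.8, 1.2), 3),
                study_ref = paste0(s, "_MS1"))
      }
      if (p$n_dup > 0) {
        for (id in sample_from(up_ids, p$n_dup)) {
          add_rec(id, s, "dup_up", fc = rfc(p$fc_up),
                  study_ref = paste0(s, "_MS2"), organism = "human")
        }
      }
      for (id in new_sites(p$n_qual_up)) {
        add_rec(id, s, "qual_up", direction = "up", assay = "immunoblot",
                study_ref = paste0(s, "_IB1"), organism = "human")
      }
      for (id in new_sites(p$n_qual_down)) {
        add_rec(id, s, "qual_down", direction = "down", assay = "immunoblot",
                study_ref = paste0(s, "_IB1"), organism = "human")
      }
      if (p$n_qual_undefined > 0) {
        for (i in seq_len(p$n_qual_undefined)) {
          add_rec(NA_integer_, s, "qual_undefined", direction = "up",
                  assay = "immunoblot", study_ref = paste0(s, "_IB2"),
                  organism = "human")
        }
      }
      per_syn_sites[[s]] <- up_ids
    }
    if (!is.null(cross) && length(ccols) == 2) {
      for (id in new_sites(cross$n_both_up)) {
        add_rec(id, ccols[1], "up", fc = rfc(c(1.8, 5)),
                study_ref = paste0(ccols[1], "_MS1"))
        add_rec(id, ccols[2], "up", fc = rfc(c(1.8, 5)),
                study_ref = paste0(ccols[2], "_MS1"))
      }
      for (id in new_sites(cross$n_both_down)) {
        add_rec(id, ccols[1], "down", fc = rfc(c(0.1, 0.6)),
                study_ref = paste0(ccols[1], "_MS1"))
        add_rec(id, ccols[2], "down", fc = rfc(c(0.1, 0.6)),
                study_ref = paste0(ccols[2], "_MS1"))
      }
      for (id in new_sites(cross$n_discordant)) {
        add_rec(id, ccols[1], "down", fc = rfc(c(0.1, 0.6)),
                study_ref = paste0(ccols[1], "_MS1"))
        add_rec(id, ccols[2], "up", fc = rfc(c(1.8, 5)),
                study_ref = paste0(ccols[2], "_MS1"))
      }
      for (id in new_sites(cross$n_up_first_unch_second)) {
        add_rec(id, ccols[1], "up", fc = rfc(c(1.8, 5)),
                study_ref = paste0(ccols[1], "_MS1"))
        add_rec(id, ccols[2], "unchanged",
                fc = round(stats::runif(1, 0.8, 1.2), 3),
                study_ref = paste0(ccols[2], "_MS1"))
      }
    }
    n_sites <- length(site_protein)
    if (is.null(proteins)) {
      proteins <- sprintf("PHOS%03d", seq_len(max(1L, ceiling(n_sites / 2))))
    }
    site_protein <- sample_from(proteins, n_sites, replace = TRUE)

    # --- phase 2: sequences and planted coordinates -------------------
    used_prot <- sort(unique(site_protein))
    seq_len_i <- sample_from(seq(cfg$seq_length[1], cfg$seq_length[2]),
                             length(used_prot), replace = TRUE)
    sequences <- stats::setNames(vapply(seq_len_i, function(L) {
      paste(sample_from(AA20, L, replace = TRUE), collapse = "")
    }, ""), used_prot)
    site_pos <- integer(n_sites)
    site_res <- character(n_sites)
    for (pr in used_prot) {
      ids <- which(site_protein == pr)
      L <- nchar(sequences[[pr]])
      pos <- sample_from(10:(L - 10), length(ids))
      res <- sample_from(c("S", "T", "Y"), length(ids), replace = TRUE)
      site_pos[ids] <- pos
      site_res[ids] <- res
      ch <- strsplit(sequences[[pr]], "")[[1]]
      ch[pos] <- res
      sequences[[pr]] <- paste(ch, collapse = "")
    }

    # sample an organism for each record that does not force one
    orgs <- cfg$organisms
    for (i in seq_along(rec)) {
      if (is.na(rec[[i]]$organism)) {
        rec[[i]]$organism <- sample_from(orgs$organism, 1L,
                                         prob = orgs$weight)
      }
    }
    # derive each needed (protein, organism) ortholog once, for all the
    # protein's sites together
    variants <- list()  # key "prot|org" -> list(acc, site positions)
    ortho_rows <- list()
    for (i in seq_along(rec)) {
      r <- rec[[i]]
      if (is.na(r$site_id) || r$organism == "human") next
      pr <- site_protein[r$site_id]
      key <- paste(pr, r$organism, sep = "|")
      if (is.null(variants[[key]])) {
        ids <- which(site_protein == pr)
        o <- orgs[orgs$organism == r$organism, ]
        mut <- mutate_sequence(sequences[[pr]], site_pos[ids],
                               o$sub_rate, o$n_indels)
        acc <- paste0(pr, "_", toupper(substr(r$organism, 1, 3)))
        sequences[[acc]] <- mut$seq
        variants[[key]] <- list(acc = acc,
                                pos = stats::setNames(mut$site_positions,
                                                      as.character(ids)))
        ortho_rows[[length(ortho_rows) + 1L]] <- data.frame(
          accession = acc, human_accession = pr, human_gene_symbol = pr,
          stringsAsFactors = FALSE
        )
      }
    }
    orthologs <- if (length(ortho_rows) > 0) {
      unique(do.call(rbind, ortho_rows))
    } else {
      data.frame(accession = character(), human_accession = character(),
                 human_gene_symbol = character(), stringsAsFactors = FALSE)
    }

    # --- phase 3: assemble the on-disk table and the truth ------------
    rows <- lapply(seq_along(rec), function(i) {
      r <- rec[[i]]
      if (is.na(r$site_id)) {
        pr <- sample_from(proteins, 1L)
        return(data.frame(accession = pr, gene_symbol = pr,
                          organism = r$organism, residue = "Y",
                          position = NA_integer_, fold_change = NA_real_,
                          direction = r$direction, assay = r$assay,
                          syndrome = r$syndrome, study_ref = r$study_ref,
                          true_human_accession = NA_character_,
                          true_human_position = NA_integer_,
                          stringsAsFactors = FALSE))
      }
      pr <- site_protein[r$site_id]
      if (r$organism == "human") {
        acc <- pr
        pos <- site_pos[r$site_id]
      } else {
        v <- variants[[paste(pr, r$organism, sep = "|")]]
        acc <- v$acc
        pos <- unname(v$pos[as.character(r$site_id)])
      }
      data.frame(accession = acc, gene_symbol = pr, organism = r$organism,
                 residue = site_res[r$site_id], position = pos,
                 fold_change = r$fc, direction = r$direction,
                 assay = r$assay, syndrome = r$syndrome,
                 study_ref = r$study_ref,
                 true_human_accession = pr,
                 true_human_position = site_pos[r$site_id],
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    truth_prot <- unique(ifelse(is.na(records$true_human_accession),
                                records$accession,
                                records$true_human_accession))

    kind <- vapply(rec, `[[`, "", "kind")
    syn <- vapply(rec, `[[`, "", "syndrome")
    sid <- vapply(rec, function(r) {
      if (is.na(r$site_id)) NA_integer_ else r$site_id
    }, 1L)
    per_syndrome <- lapply(stats::setNames(nm = sort(unique(syn))),
                           function(s) {
      in_s <- syn == s
      list(
        n_up_sites = length(unique(sid[in_s & kind %in% c("up", "dup_up")])),
        n_down_sites = length(unique(sid[in_s & kind == "down"])),
        n_unchanged_records = sum(in_s & kind == "unchanged"),
        n_qual_up = sum(in_s & kind %in% c("qual_up", "qual_undefined")),
        n_qual_down = sum(in_s & kind == "qual_down"),
        n_dup_records = sum(in_s & kind == "dup_up")
      )
    })
    dys_kinds <- c("up", "down", "dup_up")
    n_cluster <- list(
      a = cross$n_both_up, b = cross$n_both_down,
      discordant = cross$n_discordant,
      c = with(plan[[ccols[1]]], n_up + n_down + n_dup) +
        cross$n_up_first_unch_second,
      d = with(plan[[ccols[2]]], n_up + n_down + n_dup)
    )
    truth <- list(
      per_syndrome = per_syndrome,
      n_value_cells = sum(kind %in% dys_kinds),
      n_unchanged_cells = sum(kind == "unchanged"),
      n_prime_rows = sum(kind == "dup_up"),
      clusters = n_cluster,
      cross_cols = ccols,
      n_phosphoproteins = length(truth_prot),
      mapping = data.frame(
        row = seq_len(nrow(records)),
        human_accession = records$true_human_accession,
        human_position = records$true_human_position,
        stringsAsFactors = FALSE
      )
    )
    records$true_human_accession <- NULL
    records$true_human_position <- NULL
    list(records = records, sequences = sequences, orthologs = orthologs,
         truth = truth)
  })
}

#' Generate a synthetic phosphosite catalog
#'
#' Plants a per-protein count of catalogued phosphosites for every panel
#' protein, with a configurable number of heavily phosphorylated
#' proteins (at least 20 sites), and random low-/high-throughput
#' reference counts per site.
#'
#' @param cfg A [sim_config()].
#' @param panel A `seed_panel`.
#' @param n_heavy Number of proteins planted with >= 20 sites (default 7).
#' @return A list with `catalog` (data frame in the catalog CSV shape)
#'   and `truth` (per-protein planted site counts, LTP/HTP reference
#'   totals).
#' @export
generate_catalog <- function(cfg, panel, n_heavy = 7L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "seed_panel"),
            n_heavy <= nrow(panel))
  with_rng_seed(cfg$rng_seed + 2L, {
    prots <- panel$accession
    heavy <- sample_from(prots, n_heavy)
    n_sites <- ifelse(prots %in% heavy,
                      sample_from(20:60, length(prots), replace = TRUE),
                      sample_from(2:19, length(prots), replace = TRUE))
    rows <- list()
    ltp_total <- 0L; htp_total <- 0L
    for (i in seq_along(prots)) {
      pos <- sample_from(10:900, n_sites[i])
      res <- sample_from(c("S", "T", "Y"), n_sites[i], replace = TRUE)
      for (j in seq_len(n_sites[i])) {
        n_ltp <- stats::rpois(1, 0.4)
        n_htp <- stats::rpois(1, 5) + 1L
        ltp_total <- ltp_total + n_ltp
        htp_total <- htp_total + n_htp
        if (n_ltp > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein = prots[i], residue = res[j], position = pos[j],
            ref_class = "LTP", ref_count = n_ltp, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prots[i], residue = res[j], position = pos[j],
          ref_class = "HTP", ref_count = n_htp, stringsAsFactors = FALSE)
      }
    }
    catalog <- do.call(rbind, rows)
    truth <- list(
      site_counts = stats::setNames(as.integer(n_sites), prots),
      heavy = sort(heavy),
      ltp_refs = ltp_total, htp_refs = htp_total
    )
    list(catalog = catalog, truth = truth)
  })
}

#' Write a complete synthetic study to a directory
#'
#' Generates the association network, seed panel, phosphosite table
#' (with ortholog sequences), phosphosite catalog, and a set of random
#' annotation terms, and writes them in the on-disk formats the pipeline
#' readers consume: `links.tsv` (permille score dialect), `panel.csv`,
#' `phospho.csv`, `seqs.fasta`, `orthologs.tsv`, `catalog.csv`,
#' `annotations.gmt`, and `truth.json`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and `truth`
#'   (the combined network/phospho/catalog truth record).
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(cfg)
  pool <- union(net$truth$unique_union, net$panel$accession)
  n_prot <- with_rng_seed(cfg$rng_seed + 3L,
                          sample_from(pool, min(60L, length(pool))))
  pho <- generate_phospho(cfg, proteins = n_prot)
  cat_sim <- generate_catalog(cfg, net$panel,
                              n_heavy = min(7L, nrow(net$panel)))
  gmt <- with_rng_seed(cfg$rng_seed + 4L, {
    lapply(seq_len(12L), function(i) {
      list(term_id = sprintf("TERM%03d", i),
           term_name = sprintf("synthetic process %d", i),
           members = sample_from(pool, sample_from(10:40, 1L)))
    })
  })

  ed <- net$network$edges
  links <- data.frame(protein1 = ed$a, protein2 = ed$b,
                      combined_score = as.integer(round(ed$confidence * 1000)),
                      stringsAsFactors = FALSE)
  write_tsv(links, file.path(dir, "links.tsv"))
  panel_df <- data.frame(
    gene_symbol = net$panel$gene_symbol,
    accession = net$panel$accession,
    syndromes = vapply(net$panel$syndromes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(panel_df, file.path(dir, "panel.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(pho$records, file.path(dir, "phospho.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  write_fasta(pho$sequences, file.path(dir, "seqs.fasta"))
  write_tsv(pho$orthologs, file.path(dir, "orthologs.tsv"))
  utils::write.csv(cat_sim$catalog, file.path(dir, "catalog.csv"),
                   row.names = FALSE, quote = FALSE)
  write_gmt(gmt, file.path(dir, "annotations.gmt"))
  truth <- list(network = net$truth[setdiff(names(net$truth),
                                            "neighbor_sets")],
                phospho = pho$truth[setdiff(names(pho$truth), "mapping")],
                catalog = cat_sim$truth)
  write_json(truth, file.path(dir, "truth.json"))
  invisible(list(network = net$network, panel = net$panel,
                 phospho = pho, catalog = cat_sim, annotations = gmt,
                 truth = list(network = net$truth, phospho = pho$truth,
                              catalog = cat_sim$truth)))
}
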