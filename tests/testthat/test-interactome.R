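test_that("interactome totals count duplicates, union deduplicates", {
  ed <- data.frame(a = c("S1", "S1", "S1", "S2", "S2", "S2"),
                   b = c("a", "b", "c", "a", "b", "c"),
                   confidence = 0.9, stringsAsFactors = FALSE)
  net <- assoc_network(ed)
  panel <- make_panel(list(S1 = "NS", S2 = "NSML"))
  inter <- build_interactome(net, panel)
  expect_equal(inter$total_with_duplicates, 6L)
  expect_equal(length(inter$unique_union), 3L)
  expect_setequal(inter$neighbor_sets$S1, c("a", "b", "c"))
})

test_that("raising the confidence cutoff never grows a neighbor set", {
  panel <- make_panel(list(N01 = "NS", N02 = "NSML", N03 = "NS"))
  for (seed in 1:5) {
    net <- assoc_network(random_edge_table(15, 40, seed))
    lo <- build_interactome(net, panel, min_confidence = 0)
    hi <- build_interactome(net, panel, min_confidence = 0.7)
    for (s in panel$accession) {
      expect_true(all(hi$neighbor_sets[[s]] %in% lo$neighbor_sets[[s]]))
    }
  }
})

test_that("seeds absent from the network get empty sets with a warning", {
  net <- assoc_network(data.frame(a = "S1", b = "x", confidence = 0.9))
  panel <- make_panel(list(S1 = "NS", MISSING = "NSML"))
  expect_warning(inter <- build_interactome(net, panel), "absent")
  expect_equal(inter$neighbor_sets$MISSING, character(0))
  # extra sources fill in partners for seeds outside the network
  inter2 <- build_interactome(net, panel,
                              extra_sources = list(MISSING = c("y", "z")))
  expect_setequal(inter2$neighbor_sets$MISSING, c("y", "z"))
})

test_that("overlap percentages match hand enumeration and the oracle", {
  inter <- make_interactome(list(S1 = c("a", "b"), S2 = c("b", "c"),
                                 S3 = "d"))
  ov <- overlap_table(inter)
  expect_equal(ov$percent, c(50, 50, 0))
  expect_equal(attr(ov, "mean_percent"), mean(c(50, 50, 0)),
               tolerance = 1e-12)

  # a seed whose every partner appears elsewhere overlaps fully
  full <- make_interactome(list(S1 = c("a", "b"), S2 = c("a", "b", "c")))
  expect_equal(overlap_table(full)$percent[1], 100)

  expect_error(overlap_table(make_interactome(list(S1 = "a"))),
               "fewer than 2 seeds")

  for (seed in 1:5) {
    set.seed(seed)
    sets <- lapply(1:6, function(i) {
      sample(letters, sample(0:10, 1))
    })
    names(sets) <- paste0("S", 1:6)
    inter <- make_interactome(sets)
    ov <- overlap_table(inter)
    nv <- naive_overlap(lapply(sets, sort))
    expect_equal(ov$n_partners, nv$n_partners)
    expect_equal(ov$n_shared, nv$n_shared)
    expect_equal(ov$percent, nv$percent)
  }
})

test_that("pairwise intersections match the brute-force double loop", {
  for (seed in 1:5) {
    set.seed(seed)
    sets <- lapply(1:6, function(i) sample(letters, sample(1:12, 1)))
    names(sets) <- paste0("S", 1:6)
    inter <- make_interactome(sets)
    pw <- pairwise_intersections(inter)
    sizes <- naive_pair_sizes(lapply(sets, sort))
    expect_equal(nrow(pw$pairs), choose(6, 2))
    expect_equal(sort(pw$pairs$n_shared), sort(sizes))
    expect_equal(unname(pw$histogram),
                 c(sum(sizes == 0), sum(sizes >= 1 & sizes <= 5),
                   sum(sizes >= 6 & sizes <= 10), sum(sizes > 10)))
    expect_equal(sum(pw$histogram), choose(6, 2))
  }
  # fully disjoint sets land entirely in the zero bin
  dis <- make_interactome(list(S1 = "a", S2 = "b", S3 = "c"))
  expect_equal(unname(pairwise_intersections(dis)$histogram), c(3, 0, 0, 0))
})

test_that("syndrome partition pools seeds with their neighbors", {
  # single syndrome: nothing to share with
  one <- make_interactome(list(S1 = c("a", "b"), S2 = c("b", "c")),
                          make_panel(list(S1 = "NS", S2 = "NS")))
  sp1 <- syndrome_partition(one)
  expect_equal(sp1$n_shared, 0L)
  expect_equal(sp1$n_proteins, 5L)  # 2 seeds + 3 unique neighbors

  # a seed assigned to both syndromes shares its whole set
  two <- make_interactome(
    list(S1 = c("a", "b"), S2 = c("c")),
    make_panel(list(S1 = c("NS", "NSML"), S2 = "NSML"))
  )
  sp2 <- syndrome_partition(two)
  ns <- sp2[sp2$syndrome == "NS", ]
  expect_equal(ns$n_proteins, 3L)       # S1, a, b
  expect_equal(ns$n_shared, 3L)         # all of them are in the NSML set
  expect_equal(attr(sp2, "grand_total_listing"), sum(sp2$n_proteins))
  # per-syndrome listing can only exceed or equal the unique total
  expect_gte(attr(sp2, "grand_total_listing"), attr(sp2, "n_unique"))
})

test_that("hub detection uses a strict cutoff over the mean degree", {
  # star with 9 leaves plus one isolated edge: center degree 9,
  # mean degree 20/12, cutoff 4 * 20/12 = 6.67 -> only the center
  ed <- data.frame(a = c(rep("HUB", 9), "X1"),
                   b = c(paste0("L", 1:9), "X2"),
                   confidence = 0.9, stringsAsFactors = FALSE)
  hr <- hub_report(assoc_network(ed))
  expect_equal(hr$mean_degree, 20 / 12)
  expect_equal(hr$hubs$accession, "HUB")

  # 4 nodes on a path plus a high-degree node cannot beat 4x the mean
  # when the cutoff exceeds the maximum degree
  ed2 <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                    confidence = 0.9, stringsAsFactors = FALSE)
  expect_equal(nrow(hub_report(assoc_network(ed2))$hubs), 0L)

  expect_error(hub_report(assoc_network(data.frame())), "empty")
})

test_that("degrees and hubs agree with naive counting on random graphs", {
  for (seed in 1:5) {
    ed <- random_edge_table(20, 50, seed)
    net <- assoc_network(ed)
    expect_equal(network_degrees(net), naive_degrees(net$edges, net$nodes))
    hr <- hub_report(net, multiplier = 2)
    deg <- naive_degrees(net$edges, net$nodes)
    cutoff <- 2 * mean(deg)
    expect_setequal(hr$hubs$accession, names(deg)[deg > cutoff])
  }
})

test_that("lowering the hub multiplier never shrinks the hub list", {
  for (seed in 1:3) {
    net <- assoc_network(random_edge_table(20, 60, seed))
    h4 <- hub_report(net, multiplier = 4)$hubs$accession
    h2 <- hub_report(net, multiplier = 2)$hubs$accession
    expect_true(all(h4 %in% h2))
  }
})
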