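# small, fast configuration used across these tests
small_cfg <- function(seed = 17, ...) {
  args <- list(
    rng_seed = seed, n_seeds = 6, n_pool = 150, n_shared_pool = 30,
    neighbors_per_seed = c(10, 14), pairwise_overlap = 0.4,
    planted_hubs = 1, hub_degree = 45, background_edges = 120,
    decoy_edges = 40,
    phospho_plan = list(
      NS = list(n_up = 10, n_down = 5, n_unchanged = 4, n_qual_up = 1,
                n_qual_down = 1, n_qual_undefined = 1, n_dup = 1,
                fc_up = c(1.6, 6), fc_down = c(0.05, 0.6)),
      NSML = list(n_up = 6, n_down = 3, n_unchanged = 2, n_qual_up = 1,
                  n_qual_down = 0, n_qual_undefined = 0, n_dup = 0,
                  fc_up = c(1.6, 6), fc_down = c(0.05, 0.6))
    ),
    seq_length = c(150, 250)
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("generation is deterministic under a fixed seed", {
  a <- generate_network(small_cfg())
  b <- generate_network(small_cfg())
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth, b$truth)
  pa <- generate_phospho(small_cfg())
  pb <- generate_phospho(small_cfg())
  expect_identical(pa$records, pb$records)
  expect_identical(pa$sequences, pb$sequences)
  # and the global RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_network(small_cfg())); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero pairwise overlap yields disjoint neighbor sets", {
  cfg <- small_cfg(pairwise_overlap = 0, planted_hubs = 0,
                   background_edges = 100, n_pool = 200)
  sim <- generate_network(cfg)
  expect_true(all(sim$truth$pairwise$n_shared == 0))
  pw <- pairwise_intersections(
    build_interactome(sim$network, sim$panel, 0.7))
  expect_true(all(pw$pairs$n_shared == 0))
})

test_that("full overlap from a tight shared pool gives identical sets", {
  cfg <- sim_config(rng_seed = 3, n_seeds = 2, n_pool = 60,
                    n_shared_pool = 10, neighbors_per_seed = c(10, 10),
                    pairwise_overlap = 1, planted_hubs = 0,
                    background_edges = 60, decoy_edges = 0)
  sim <- generate_network(cfg)
  expect_identical(sim$truth$neighbor_sets[[1]],
                   sim$truth$neighbor_sets[[2]])
  ov <- overlap_table(build_interactome(sim$network, sim$panel, 0.7))
  expect_equal(ov$percent, c(100, 100))
})

test_that("planted hubs exceed the realized cutoff; infeasible demands fail", {
  sim <- generate_network(small_cfg())
  expect_true(all(sim$truth$planted_hubs %in% sim$truth$hubs$accession))
  expect_true(all(sim$truth$hubs$degree > sim$truth$cutoff))
  cfg_bad <- small_cfg(hub_degree = 5000)
  expect_error(generate_network(cfg_bad), "infeasible")
})

test_that("configuration validation rejects out-of-band fold changes", {
  expect_error(sim_config(phospho_plan = list(
    NS = list(n_up = 2, n_down = 0, n_unchanged = 0, n_qual_up = 0,
              n_qual_down = 0, n_qual_undefined = 0, n_dup = 0,
              fc_up = c(1.2, 3), fc_down = c(0.1, 0.5)))),
    "fc_up")
  expect_error(sim_config(phospho_plan = list(
    NS = list(n_up = 0, n_down = 2, n_unchanged = 0, n_qual_up = 0,
              n_qual_down = 0, n_qual_undefined = 0, n_dup = 0,
              fc_up = c(1.6, 3), fc_down = c(0.1, 0.9)))),
    "fc_down")
})

test_that("planted dysregulation counts survive the full phospho pipeline", {
  pho <- generate_phospho(small_cfg())
  rec <- map_records_to_human(pho$records, pho$sequences, pho$orthologs)
  expect_true(all(rec$mapped[!is.na(rec$position)]))
  sm <- summarize_by_syndrome(apply_threshold(rec))
  truth <- pho$truth$per_syndrome
  for (s in names(truth)) {
    row <- sm[sm$syndrome == s, ]
    expect_equal(row$n_up_quant - truth[[s]]$n_dup_records,
                 truth[[s]]$n_up_sites)
    expect_equal(row$n_down_quant, truth[[s]]$n_down_sites)
  }
})

test_that("indel-shifted ortholog coordinates map back to planted sites", {
  pho <- generate_phospho(small_cfg(seed = 23))
  truth_map <- pho$truth$mapping
  rec <- map_records_to_human(pho$records, pho$sequences, pho$orthologs)
  positioned <- which(!is.na(rec$position))
  expect_gt(length(positioned), 10)
  expect_true(any(rec$organism[positioned] == "zebrafish"))
  for (i in positioned) {
    expect_equal(rec$human_accession[i], truth_map$human_accession[i])
    expect_equal(rec$human_position[i], truth_map$human_position[i])
  }
  # non-human records really are shifted: at least one source position
  # differs from its human counterpart
  nh <- positioned[rec$organism[positioned] != "human"]
  expect_true(any(rec$position[nh] != rec$human_position[nh]))
})

test_that("the matrix carries exactly the planted unchanged cells", {
  pho <- generate_phospho(small_cfg())
  rec <- apply_threshold(
    map_records_to_human(pho$records, pho$sequences, pho$orthologs))
  dm <- build_matrix(rec)
  expect_equal(sum(dm$unchanged), pho$truth$n_unchanged_cells)
  expect_equal(sum(!is.na(dm$log2fc)), pho$truth$n_value_cells)
  expect_equal(sum(grepl("'", rownames(dm$log2fc))),
               pho$truth$n_prime_rows)
})

test_that("the synthetic catalog plants heavy proteins and reference totals", {
  panel <- default_seed_panel()
  cs <- generate_catalog(small_cfg(), panel, n_heavy = 5)
  census <- build_census(cs$catalog, panel)
  expect_equal(stats::setNames(census$entries$n_sites,
                               census$entries$accession)[names(cs$truth$site_counts)],
               cs$truth$site_counts)
  expect_setequal(census$totals$flagged, cs$truth$heavy)
  expect_equal(census$totals$ltp_refs, cs$truth$ltp_refs)
  expect_equal(census$totals$htp_refs, cs$truth$htp_refs)
})
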