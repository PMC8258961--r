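random_protein <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "W", "V", "S", "T", "Y"),
               len, replace = TRUE), collapse = "")
}

test_that("site mapping is the identity on identical sequences", {
  for (seed in 1:5) {
    seq <- random_protein(120, seed)
    acceptors <- which(strsplit(seq, "")[[1]] %in% c("S", "T", "Y"))
    for (pos in sample(acceptors, min(3, length(acceptors)))) {
      res <- substr(seq, pos, pos)
      m <- map_site_to_human(seq, seq, render_site(res, pos))
      expect_true(m$mapped)
      expect_equal(m$human_position, pos)
      expect_equal(m$human_residue, res)
      expect_false(m$conservative)
    }
  }
})

test_that("an N-terminal insertion shifts mapped positions by its length", {
  src <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"  # Y at position 5
  hum <- paste0("GGG", src)
  m <- map_site_to_human(src, hum, "Y5")
  expect_true(m$mapped)
  expect_equal(m$human_position, 8L)
  # shift-equivariance for arbitrary prefix lengths on random sequences
  for (seed in 1:4) {
    seq <- random_protein(150, seed)
    acceptors <- which(strsplit(seq, "")[[1]] %in% c("S", "T", "Y"))
    pos <- acceptors[acceptors > 20][1]
    res <- substr(seq, pos, pos)
    for (k in c(1, 7, 15)) {
      hum <- paste0(random_protein(k, seed + 100), seq)
      m <- map_site_to_human(seq, hum, render_site(res, pos))
      expect_true(m$mapped)
      expect_equal(m$human_position, pos + k)
    }
  }
})

test_that("sites aligned to gaps or non-acceptors are unmapped, not errors", {
  # the source tail (with the site) is absent from the truncated ortholog
  src <- paste0(random_protein(60, 1), "GGGGYAAAA")
  hum <- substr(src, 1, 60)
  m <- map_site_to_human(src, hum, "Y65")
  expect_false(m$mapped)
  expect_equal(m$reason, "gap")

  # residue replaced by a non-acceptor in human
  src2 <- "MKAAYIAKQRQISFVKSHFSRQLEE"
  hum2 <- sub("Y", "F", src2)
  m2 <- map_site_to_human(src2, hum2, "Y5")
  expect_false(m2$mapped)
  expect_equal(m2$reason, "non_acceptor")

  # conservative S/T exchange is accepted and flagged
  src3 <- "MKAASIAKQRQISFVKDHFARQLEE"
  hum3 <- sub("S", "T", src3)
  m3 <- map_site_to_human(src3, hum3, "S5")
  expect_true(m3$mapped)
  expect_true(m3$conservative)
  expect_equal(m3$human_residue, "T")

  expect_error(map_site_to_human("MKAY", "MKAY", "S2"), "not 'S'")
})

test_that("fold-change normalization divides condition ratios", {
  expect_equal(normalize_fold_change(4, 2, 1, 1), 2)
  expect_equal(normalize_fold_change(1, 1, 1, 1), 1)
  expect_equal(normalize_fold_change(3, 2, 3, 4), 2)  # 1.5 / 0.75
  expect_error(normalize_fold_change(0, 1, 1, 1), "positive")
  expect_error(normalize_fold_change(1, 1, -2, 1), "positive")
})

test_that("the threshold partitions records with inclusive boundaries", {
  rec <- make_records(paste0("P", 1:5), "NS",
                      fold_change = c(7.72, 1.0, 1 / 1.5, 1.5, 1.49))
  rec <- apply_threshold(rec)
  expect_equal(rec$status, c("up", "not_dysregulated", "down", "up",
                             "not_dysregulated"))
  # measured-but-unchanged is distinct from missing
  expect_equal(rec$reported_unchanged,
               c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(apply_threshold(rec, threshold = 1), "> 1")

  # qualitative records pass through on their stated direction
  q <- make_records("P9", "NS", direction = "down", assay = "immunoblot")
  expect_equal(apply_threshold(q)$status, "down")
})

test_that("a record is up at fc exactly when its reciprocal is down", {
  for (seed in 1:5) {
    set.seed(seed)
    fc <- round(runif(20, 0.05, 8), 3)
    up <- apply_threshold(make_records(paste0("P", 1:20), "NS",
                                       fold_change = fc))$status == "up"
    down <- apply_threshold(make_records(paste0("P", 1:20), "NS",
                                         fold_change = 1 / fc))$status == "down"
    expect_equal(up, down)
  }
})

test_that("the dysregulation matrix separates values, 0* and missing", {
  rec <- make_records(c("P1", "P1", "P2", "P3"),
                      c("NS", "NSML", "NS", "NSML"),
                      fold_change = c(2.0, 4.0, 1.1, 0.25),
                      position = c(10L, 10L, 20L, 30L))
  rec <- map_records_to_human(rec)
  dm <- build_matrix(rec)
  expect_equal(dm$log2fc["P1:Y10", "NS"], 1.0)
  expect_equal(dm$log2fc["P1:Y10", "NSML"], 2.0)
  expect_true(dm$unchanged["P2:Y20", "NS"])   # fc 1.1 inside the band
  expect_true(is.na(dm$log2fc["P2:Y20", "NSML"]))
  rendered <- as.data.frame(dm)
  expect_equal(rendered[rendered$site == "P2:Y20", "NS"], "0*")
  expect_equal(rendered[rendered$site == "P2:Y20", "NSML"], "NA")
  # conservation: non-missing cells = passing + reported-unchanged
  expect_equal(sum(!is.na(dm$log2fc)) + sum(dm$unchanged), 4L)
})

test_that("replicate studies become prime-tagged matrix rows", {
  rec <- make_records(c("P1", "P1"), "NS", fold_change = c(2, 3),
                      study_ref = c("s1", "s2"))
  rec <- map_records_to_human(rec)
  dm <- build_matrix(rec)
  expect_setequal(rownames(dm$log2fc), c("P1:Y10", "P1:Y10'"))
})

test_that("cluster assignment covers a, b, c, d and discordant", {
  rec <- make_records(
    accession = c("A", "A", "B", "B", "C", "D", "E", "E", "F", "F"),
    syndrome = c("NS", "NSML", "NS", "NSML", "NS", "NSML",
                 "NS", "NSML", "NS", "NSML"),
    fold_change = c(2, 3, 0.2, 0.4, 2.5, 0.3, 0.4, 1.8, 1.7, 1.05),
    position = c(10L, 10L, 20L, 20L, 30L, 40L, 50L, 50L, 60L, 60L)
  )
  rec <- map_records_to_human(rec)
  cl <- assign_clusters(build_matrix(rec))
  got <- stats::setNames(cl$cluster, cl$site)
  expect_equal(unname(got["A:Y10"]), "a")
  expect_equal(unname(got["B:Y20"]), "b")
  expect_equal(unname(got["C:Y30"]), "c")   # NSML missing
  expect_equal(unname(got["D:Y40"]), "d")   # NS missing
  expect_equal(unname(got["E:Y50"]), "discordant")
  expect_equal(unname(got["F:Y60"]), "c")   # NSML measured but unchanged
  expect_error(assign_clusters(build_matrix(rec), cols = c("NS", "CS")),
               "lacks syndrome")
})

test_that("syndrome summaries recover planted counts and extremes", {
  rec <- make_records(
    accession = c(paste0("U", 1:10), paste0("D", 1:5), "N1"),
    syndrome = "NS",
    fold_change = c(seq(2, 7.72, length.out = 10), seq(0.02, 0.5,
                                                       length.out = 5), 1.0),
    position = 10:25
  )
  rec <- map_records_to_human(rec)
  sm <- summarize_by_syndrome(rec)
  expect_equal(sm$n_up_quant, 10L)
  expect_equal(sm$n_down_quant, 5L)
  expect_equal(sm$n_sites_quant, 15L)
  expect_equal(sm$n_proteins_quant, 15L)
  expect_equal(sm$max_fc, 7.72)
  expect_equal(sm$max_site, "U10:Y19")
  expect_equal(sm$min_fc, 0.02)
  expect_equal(attr(sm, "totals")$n_up_quant, 10L)
  expect_equal(attr(sm, "totals")$n_down_quant, 5L)

  empty <- summarize_by_syndrome(make_records(character(0), character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("cross-linking keeps records whose protein is in the interactome", {
  inter <- make_interactome(list(S1 = c("P1", "P2")))
  rec <- make_records(c("P1", "P1", "P2", "X1", "S1"), "NS",
                      fold_change = 2, position = c(10L, 20L, 10L, 10L, 10L))
  rec <- map_records_to_human(rec)
  cl <- crosslink_interactome(rec, inter)
  # P1 (twice), P2, and the seed S1 itself stay; X1 is outside
  expect_equal(nrow(cl$records), 4L)
  expect_equal(cl$n_phosphoproteins, 3L)
  disjoint <- crosslink_interactome(
    map_records_to_human(make_records("ZZZ", "NS", fold_change = 2)), inter)
  expect_equal(nrow(disjoint$records), 0L)
})
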