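test_that("association tables parse both score dialects identically", {
  tmp_p <- withr::local_tempfile(fileext = ".tsv")
  tmp_f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t700", "B\tC\t950", "A\tC\t412"), tmp_p)
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t0.700", "B\tC\t0.950", "A\tC\t0.412"), tmp_f)
  net_p <- read_association_table(tmp_p)
  net_f <- read_association_table(tmp_f)
  expect_identical(net_p$edges, net_f$edges)
  expect_equal(net_p$edges$confidence[net_p$edges$a == "A" &
                                      net_p$edges$b == "B"], 0.700)
})

test_that("undirected duplicates collapse to the maximum confidence", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.5", "B\tA\t0.9"), tmp)
  net <- read_association_table(tmp)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$confidence, 0.9)
})

test_that("self-loops and duplicates are removed with the expected count", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # 10 rows: 2 self-loops, 1 duplicated pair, 6 further unique pairs
  writeLines(c("A\tA\t700", "B\tB\t500",
               "C\tD\t600", "D\tC\t800",
               "A\tB\t710", "A\tC\t720", "B\tC\t730",
               "D\tE\t740", "E\tF\t750", "F\tA\t760"), tmp)
  expect_warning(net <- read_association_table(tmp), "self-loop")
  expect_equal(nrow(net$edges), 7L)
  expect_equal(net$edges$confidence[net$edges$a == "C" &
                                    net$edges$b == "D"], 0.8)
})

test_that("malformed and empty association tables raise named errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t700", "C\tD\tnot_a_number"), tmp)
  expect_error(read_association_table(tmp), "line 2")
  writeLines(c("A\tB"), tmp)
  expect_error(read_association_table(tmp), "line 1")
  writeLines(character(), tmp)
  expect_error(read_association_table(tmp), "empty")
})

test_that("reading a file twice and merging equals reading it once", {
  for (seed in 1:3) {
    ed <- random_edge_table(12, 20, seed)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(ed, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    once <- read_association_table(tmp)
    twice <- assoc_network(rbind(read_association_table(tmp)$edges,
                                 read_association_table(tmp)$edges))
    expect_identical(once$edges, twice$edges)
  }
})

test_that("the packaged seed panels carry 27 and 32 proteins", {
  panel <- default_seed_panel()
  expect_equal(nrow(panel), 27L)
  ext <- default_seed_panel(extended = TRUE)
  expect_equal(nrow(ext), 32L)
  expect_true(all(panel$accession %in% ext$accession))
  # NS is the most genetically diverse syndrome on the panel
  n_ns <- sum(vapply(panel$syndromes, function(s) "NS" %in% s, TRUE))
  expect_equal(n_ns, 13L)
  # display groups expand to member accessions that are panel entries
  al <- attr(panel, "aliases")
  expect_setequal(names(al), c("RAS", "RRAS", "MEK1/2"))
  expect_setequal(panel$gene_symbol[match(al$RAS, panel$accession)],
                  c("HRAS", "KRAS", "NRAS"))
  expect_true(all(unlist(al) %in% panel$accession))
})

test_that("seed panel validation rejects bad rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_symbol,accession,syndromes",
               "AAA,P1,NS;NSML", "BBB,P2,NS"), tmp)
  panel <- read_seed_panel(tmp)
  expect_setequal(panel$syndromes[[1]], c("NS", "NSML"))

  writeLines(c("gene_symbol,accession,syndromes",
               "AAA,P1,NS", "BBB,P1,NSML"), tmp)
  expect_error(read_seed_panel(tmp), "duplicate accession")

  writeLines(c("gene_symbol,accession,syndromes",
               "AAA,P1,"), tmp)
  expect_error(read_seed_panel(tmp), "without syndrome")

  writeLines(c("gene_symbol,accession,syndromes",
               "AAA,P1,NOT_A_SYNDROME"), tmp)
  expect_error(read_seed_panel(tmp), "unknown syndrome")
})

test_that("phosphosite tables validate and tag replicate studies", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  hdr <- "accession,gene_symbol,organism,residue,position,fold_change,direction,assay,syndrome,study_ref"
  writeLines(c(hdr,
               "O95297,MPZL1,human,Y,241,7.72,,MS,NS,study1",
               "O95297,MPZL1,human,Y,241,6.1,,MS,NS,study2",
               "P04049,RAF1,mouse,S,259,,up,immunoblot,NS,study3",
               "O95297,MPZL1,human,Y,,,up,immunoblot,NS,study4"), tmp)
  rec <- read_phospho_table(tmp)
  expect_equal(nrow(rec), 4L)
  expect_true(rec$quantitative[1])
  expect_equal(rec$fold_change[1], 7.72)
  expect_false(rec$quantitative[3])
  # second study on the same site and syndrome gets a prime tag
  expect_equal(rec$replicate_tag[1:2], c("", "'"))
  # undefined site rows are allowed and untagged
  expect_true(is.na(rec$position[4]))

  writeLines(c(hdr, "P1,G1,human,Y,10,-2,,MS,NS,s"), tmp)
  expect_error(read_phospho_table(tmp), "fold_change must be > 0")
  writeLines(c(hdr, "P1,G1,human,Q,10,2,,MS,NS,s"), tmp)
  expect_error(read_phospho_table(tmp), "row\\(s\\) 1")
  writeLines(c(hdr, "P1,G1,human,Y,10,,,MS,NS,s"), tmp)
  expect_error(read_phospho_table(tmp), "either fold_change or direction")
  writeLines(c(hdr, "P1,G1,martian,Y,10,2,,MS,NS,s"), tmp)
  expect_error(read_phospho_table(tmp), "unknown organism")
})

test_that("FASTA, GMT and TSV round-trip exactly", {
  seqs <- c(P1 = "MKTAYIAK", P2_MOUSE = "MKSAYIAK")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)

  sets <- list(list(term_id = "T1", term_name = "first term",
                    members = c("P1", "P2")),
               list(term_id = "T2", term_name = "second term",
                    members = c("P2", "P3", "P4")))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)
  writeLines("T1\tonly a name", gmt)
  expect_error(read_gmt(gmt), "line 1")

  df <- data.frame(seed = c("A", "B"), n_partners = c(3L, 0L),
                   percent = c(66.5, NA), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(df, tsv)
  expect_identical(read_tsv(tsv), df)
})
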