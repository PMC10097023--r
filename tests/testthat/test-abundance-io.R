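test_that("write/read round-trips a table, in both orientations", {
  tab <- toy_table()
  tf <- tempfile(fileext = ".tsv")
  tx <- tempfile(fileext = ".tsv")
  write_abundance(tab, tf, taxonomy_path = tx, comment = "seed = 1")
  back <- read_abundance(tf, tx)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$taxonomy$genus, tab$taxonomy$genus)

  # OTU-in-rows file is auto-detected via the taxonomy ids
  tf2 <- tempfile(fileext = ".tsv")
  df <- data.frame(otu_id = colnames(tab$counts), t(tab$counts),
                   check.names = FALSE)
  write.table(df, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_abundance(tf2, tx)
  expect_equal(back2$counts, tab$counts)
})

test_that("malformed tables are rejected with the offending id", {
  counts <- matrix(c(1, -2, 3, 4), 2, 2,
                   dimnames = list(c("s1", "s2"), c("o1", "o2")))
  expect_error(abundance_table(counts), "negative count.*s2.*o1")
  dup <- matrix(1, 2, 2, dimnames = list(c("s1", "s1"), c("o1", "o2")))
  expect_error(abundance_table(dup), "duplicate sample id")
  ok <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("o1", "o2")))
  expect_error(
    abundance_table(ok, data.frame(otu_id = "zzz", genus = "g")),
    "unknown OTU: zzz"
  )
})

test_that("lineage strings parse into ranks", {
  lin <- "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__"
  parsed <- parse_lineage(lin)
  expect_equal(parsed$genus, "Lactobacillus")
  expect_equal(parsed$phylum, "Firmicutes")
  expect_equal(parsed$species, "")
  short <- parse_lineage("k__Bacteria;p__Bacteroidetes")
  expect_equal(short$genus, "")
})

test_that("rank aggregation is additive, pools unclassified and conserves totals", {
  tab <- toy_table()
  gen <- aggregate_rank(tab, "genus")
  expect_equal(unname(gen$counts["s1", "Lactobacillus"]), 3 + 4)
  expect_true("unclassified" %in% colnames(gen$counts))
  expect_equal(rowSums(gen$counts), rowSums(tab$counts))
  expect_error(aggregate_rank(tab, "kingdomx"), "unknown rank")

  d <- synthetic_design(n_samples = 25, n_otus = 80,
                        modules = data.frame(size = 20, latent_corr = 0.8),
                        seed = 3)
  g <- generate_abundance(d)
  for (rank in c("phylum", "family", "genus")) {
    agg <- aggregate_rank(g$abundance, rank)
    expect_equal(rowSums(agg$counts), rowSums(g$abundance$counts))
  }
})

test_that("relative abundance normalises rows and flags empty samples", {
  m <- rbind(s1 = c(o1 = 1, o2 = 3), s2 = c(o1 = 2, o2 = 2))
  rel <- relative_abundance(m)
  expect_equal(unname(rel["s1", ]), c(0.25, 0.75))
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-12)
  m0 <- m
  m0["s2", ] <- 0
  expect_error(relative_abundance(m0), "s2")
})

test_that("group overlap partitions OTUs over presence patterns", {
  counts <- rbind(
    a1 = c(o1 = 5, o2 = 0, o3 = 1, o4 = 0),
    a2 = c(o1 = 1, o2 = 0, o3 = 2, o4 = 0),
    b1 = c(o1 = 0, o2 = 3, o3 = 4, o4 = 0)
  )
  tab <- abundance_table(counts)
  traits <- data.frame(sample_id = c("a1", "a2", "b1"),
                       group = c("A", "A", "B"))
  ov <- group_otu_overlap(tab, traits, "group")
  expect_equal(unname(ov["A"]), 1)     # o1 exclusive to A
  expect_equal(unname(ov["B"]), 1)     # o2 exclusive to B
  expect_equal(unname(ov["A&B"]), 1)   # o3 shared; o4 absent everywhere
  expect_equal(sum(ov), 3)
  expect_error(group_otu_overlap(tab, data.frame(sample_id = rownames(counts),
                                                 group = "A"), "group"),
               "2 groups")

  # conservation on a random table
  d <- synthetic_design(n_samples = 30, n_otus = 60,
                        modules = data.frame(size = 20, latent_corr = 0.7),
                        seed = 8)
  g <- generate_abundance(d)
  ov2 <- group_otu_overlap(g$abundance, g$traits, "group")
  expect_equal(sum(ov2), sum(colSums(g$abundance$counts) > 0))
})
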