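test_that("mito_genome validates its invariants", {
  feats <- data.frame(name = c("cox1", "trnI"), kind = c("CDS", "tRNA"),
                      start = c(21, 5), end = c(50, 15),
                      strand = c("+", "-"))
  g <- mito_genome("toy", strrep("ACGT", 15), feats)
  expect_s3_class(g, "mito_genome")
  expect_equal(g$length, 60)
  expect_equal(g$features$name, c("trnI", "cox1"))  # sorted by start

  expect_error(mito_genome("x", ""), "empty")
  expect_error(mito_genome("x", "ACGRT"), "invalid characters")
  bad <- feats; bad$end[1] <- 99
  expect_error(mito_genome("x", strrep("ACGT", 15), bad), "bounds")
  wrap <- data.frame(name = "ctl", kind = "control_region",
                     start = 55, end = 5, strand = "+")
  expect_error(mito_genome("x", strrep("ACGT", 15), wrap, circular = FALSE),
               "origin-wrapping")
  expect_silent(mito_genome("x", strrep("ACGT", 15), wrap, circular = TRUE))
})

test_that("GenBank reader parses features, strands and the circular flag", {
  set.seed(42)
  seq <- rand_seq(300)
  feats <- data.frame(name = c("COX1", "tRNA-Ile", "16S ribosomal RNA"),
                      kind = c("CDS", "tRNA", "rRNA"),
                      start = c(10, 160, 200), end = c(159, 190, 290),
                      strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_genbank("TEST01", seq, feats), path)
  g <- read_mito_genome(path, format = "genbank")
  expect_equal(g$identifier, "TEST01")
  expect_true(g$circular)
  expect_equal(g$sequence, seq)
  expect_equal(g$features$name, c("cox1", "trnI", "rrnL"))
  expect_equal(g$features$strand, c("+", "-", "-"))
})

test_that("unknown feature kinds are dropped with a warning", {
  seq <- strrep("ACGT", 50)
  lines <- make_genbank("TEST02", seq,
                        data.frame(name = "cox1", kind = "CDS", start = 1,
                                   end = 90, strand = "+"))
  lines <- append(lines, c("     gap             100..110",
                           "                     /estimated_length=10"),
                  after = grep("ORIGIN", lines) - 1)
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines, path)
  expect_warning(g <- read_mito_genome(path), "unknown kind")
  expect_equal(nrow(g$features), 1)
})

test_that("fasta+table round trip reproduces sequence and features", {
  set.seed(7)
  feats <- data.frame(name = c("nad2", "trnW"), kind = c("CDS", "tRNA"),
                      start = c(11, 130), end = c(109, 195),
                      strand = c("+", "-"))
  g <- mito_genome("rt", rand_seq(200), feats)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mito_genome(g, fa, tsv)
  g2 <- read_mito_genome(fa, format = "fasta+table", table = tsv)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$features, g$features)
})

test_that("gene name normalization maps common synonyms", {
  expect_equal(normalize_gene_name(c("ND4L", "COB", "COIII", "ATPase6")),
               c("nad4l", "cytb", "cox3", "atp6"))
  expect_equal(normalize_gene_name(c("tRNA-Leu1", "trnS2", "tRNA-Met")),
               c("trnL1", "trnS2", "trnM"))
  expect_equal(normalize_gene_name("12S rRNA"), "rrnS")
})

test_that("partition extraction is strand-aware and round-trips", {
  seq <- paste0("AAAA", "ATGGCCTAA", "TTTT", "CCCGGG", "AA")
  feats <- data.frame(name = c("atp8", "rrnS"), kind = c("CDS", "rRNA"),
                      start = c(5, 18), end = c(13, 23),
                      strand = c("-", "+"))
  g <- mito_genome("px", seq, feats)
  expect_equal(extract_partition(g, "full"), seq)
  # minus-strand gene comes back reverse-complemented
  expect_equal(extract_partition(g, "gene:atp8"),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGGCCTAA"))))
  expect_equal(extract_partition(g, "PCG"), extract_partition(g, "gene:atp8"))
  expect_equal(extract_partition(g, "rRNA"), "CCCGGG")
  expect_error(extract_partition(g, "tRNA"), "empty partition")
  expect_error(extract_partition(g, "bogus"), "unknown partition")
})

test_that("reverse-complement extraction is an involution", {
  set.seed(11)
  for (i in 1:5) {
    s <- rand_seq(60)
    g <- mito_genome("inv", s,
                     data.frame(name = "nad3", kind = "CDS", start = 7,
                                end = 54, strand = "-"))
    once <- extract_partition(g, "gene:nad3")
    g2 <- mito_genome("inv2", once,
                      data.frame(name = "nad3", kind = "CDS", start = 1,
                                 end = nchar(once), strand = "-"))
    expect_equal(extract_partition(g2, "gene:nad3"), substr(s, 7, 54))
  }
})

test_that("PCG partition length equals the sum of CDS lengths", {
  g <- generate_genome(synthetic_spec(seed = 21))$genome
  cds_len <- with(subset(g$features, kind == "CDS"), sum(end - start + 1))
  expect_equal(nchar(extract_partition(g, "PCG")), cds_len)
})

test_that("inventory reports spacers, overlaps and kind counts", {
  feats <- data.frame(name = c("a", "b", "c"),
                      kind = c("CDS", "tRNA", "rRNA"),
                      start = c(1, 8, 23), end = c(10, 20, 30),
                      strand = "+")
  g <- mito_genome("iv", strrep("ACGT", 10), feats)
  inv <- inventory_report(g)
  # [1..10] then [8..20]: overlap of 3 bp; [8..20] then [23..30]: spacer 2 bp
  expect_equal(inv$spacer_to_next, c(-3L, 2L, NA))
  expect_equal(sum(attr(inv, "kind_counts")), nrow(feats))
})

test_that("engineered spacer extremes are reported as-is", {
  set.seed(3)
  seq <- rand_seq(1500)
  feats <- data.frame(name = c("g1", "g2", "g3"), kind = "CDS",
                      start = c(1, 33, 1415), end = c(30, 133, 1490),
                      strand = "+")
  inv <- inventory_report(mito_genome("sp", seq, feats))
  spacers <- inv$spacer_to_next[!is.na(inv$spacer_to_next)]
  expect_equal(range(spacers), c(2, 1281))
})

test_that("gene inventory counts 37 canonical genes and flags absences", {
  g <- generate_genome(synthetic_spec(seed = 13))$genome
  inv <- gene_inventory(g)
  expect_equal(inv$n_genes, 37)
  expect_length(inv$missing, 0)

  # drop trnI: inventory 36, missing report names it
  g2 <- g
  g2$features <- g2$features[g2$features$name != "trnI", ]
  inv2 <- gene_inventory(g2)
  expect_equal(inv2$n_genes, 36)
  expect_equal(inv2$missing, "trnI")
})

test_that("pseudogenes stay in the model but out of PCG partitions", {
  seq <- paste0(strrep("A", 4), "ATGAAATAA", strrep("C", 4), "ATGTTTTAA",
                strrep("G", 4))
  feats <- data.frame(name = c("nad5", "nad5-1"),
                      kind = c("CDS", "pseudogene"),
                      start = c(5, 18), end = c(13, 26), strand = "+")
  g <- mito_genome("ps", seq, feats)
  expect_equal(nrow(g$features), 2)
  expect_equal(extract_partition(g, "PCG"), "ATGAAATAA")
})
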