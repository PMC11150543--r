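test_that("a fixed seed reproduces the genome bit-identically", {
  sp <- synthetic_spec(seed = 99, ssrs = list(
    list(motif = "TAT", n_units = 6, location = "nad6")))
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$truth$ssrs, g2$truth$ssrs)
  g3 <- generate_genome(synthetic_spec(seed = 100, ssrs = sp$ssrs))
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("embedded repeats are the only repeats, at their recorded coordinates", {
  sp <- synthetic_spec(seed = 17, ssrs = list(
    list(motif = "AAAT", n_units = 3, location = "nad4"),
    list(motif = "TAT", n_units = 6, location = "nad6"),
    list(motif = "AATT", n_units = 3, location = "intergenic")))
  g <- generate_genome(sp)
  recs <- scan_ssrs(g$genome)
  expect_equal(nrow(recs), 3)
  expect_equal(recs[, c("motif", "n_units", "size", "start", "end")],
               g$truth$ssrs[order(g$truth$ssrs$start),
                            c("motif", "n_units", "size", "start", "end")],
               ignore_attr = TRUE)
  # embedded sequence is literally present
  expect_equal(substr(g$genome$sequence, recs$start[2], recs$end[2]),
               strrep(recs$motif[2], recs$n_units[2]))
})

test_that("realized composition matches the target percentages closely", {
  g <- generate_genome(synthetic_spec(seed = 23))
  st <- base_composition(g$genome$sequence)
  tgt <- g$truth$base_pct_target
  expect_lt(abs(st$pct_A - tgt[["A"]]), 1)
  expect_lt(abs(st$pct_T - tgt[["T"]]), 1)
  expect_lt(abs(st$pct_C - tgt[["C"]]), 1)
  expect_lt(abs(st$pct_G - tgt[["G"]]), 1)
})

test_that("generated CDS are valid open reading frames under code 5", {
  g <- generate_genome(synthetic_spec(seed = 29))$genome
  gc5 <- genetic_code(5)
  for (cds in cds_sequences(g, trim = FALSE)) {
    cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    expect_true(substr(cds, 1, 3) %in% c("ATA", "ATT", "ATG", "TTG"))
    expect_equal(unname(gc5[cods[length(cods)]]), "*")
    expect_false(any(gc5[cods[-length(cods)]] == "*"))
  }
})

test_that("infeasible embeddings fail loudly", {
  expect_error(
    generate_genome(synthetic_spec(seed = 1, ssrs = list(
      list(motif = "TA", n_units = 40, location = "trnI")))),
    "infeasible")
})

test_that("mutate_cds_pair plants exactly the requested change classes", {
  g <- generate_genome(synthetic_spec(seed = 37))$genome
  cds <- cds_sequences(g)[["nad5"]]
  gc5 <- genetic_code(5)
  mp <- mutate_cds_pair(cds, n_syn = 7, n_nonsyn = 5, seed = 11)
  expect_equal(nchar(mp$copyB), nchar(cds))
  expect_equal(sum(mp$truth$class == "synonymous"), 7)
  expect_equal(sum(mp$truth$class == "nonsynonymous"), 5)
  a <- strsplit(mp$copyA, "")[[1]]
  b <- strsplit(mp$copyB, "")[[1]]
  diffs <- which(a != b)
  expect_equal(sort(diffs), sort(mp$truth$position))
  # one change per codon, classes verified independently by translation
  expect_equal(length(unique((diffs - 1) %/% 3)), length(diffs))
  for (i in seq_len(nrow(mp$truth))) {
    ci <- mp$truth$codon_index[i]
    ca <- substr(mp$copyA, ci * 3 - 2, ci * 3)
    cb <- substr(mp$copyB, ci * 3 - 2, ci * 3)
    same <- gc5[[ca]] == gc5[[cb]]
    expect_equal(mp$truth$class[i],
                 if (same) "synonymous" else "nonsynonymous")
    expect_false(gc5[[cb]] == "*")
  }
  # zero-change request returns identical copies
  mp0 <- mutate_cds_pair(cds, 0, 0, seed = 2)
  expect_identical(mp0$copyA, mp0$copyB)
  expect_error(mutate_cds_pair("ATGAAATAA", 5, 0, seed = 1), "infeasible")
})

test_that("panel counts follow the size model and truth joins 1:1", {
  p <- suppressWarnings(generate_panel(8, seed = 303))
  expect_length(p$genomes, 8)
  for (i in 1:8) {
    expect_equal(p$genomes[[i]]$length, p$model$sizes[i])
    expect_equal(nrow(p$truth[[i]]$ssrs), p$model$counts[i])
    recs <- scan_ssrs(p$genomes[[i]])
    expect_equal(nrow(recs), nrow(p$truth[[i]]$ssrs))
  }
  # reproducibility
  p2 <- suppressWarnings(generate_panel(8, seed = 303))
  expect_identical(p$genomes[[3]]$sequence, p2$genomes[[3]]$sequence)
  expect_error(generate_panel(2), ">= 3")
})

test_that("a zero-slope panel shows near-zero count-size correlation", {
  p <- suppressWarnings(generate_panel(16, slope = 0, intercept = 8,
                                       noise_sd = 2, seed = 71))
  recs <- lapply(p$genomes, scan_ssrs)
  sm <- cross_species_summary(p$genomes, recs)
  expect_lt(sm$r_squared, 0.3)
})

test_that("panel location classes track the coding fraction by construction", {
  p <- suppressWarnings(generate_panel(10, seed = 404, coding_fraction = 0.7))
  locs <- unlist(lapply(p$truth, function(t) t$ssrs$location))
  frac <- mean(!locs %in% c("intergenic", "control_region"))
  expect_lt(abs(frac - 0.7), 0.15)
  # classify_locations agrees with the generator's intent
  for (i in seq_along(p$genomes)) {
    recs <- classify_locations(scan_ssrs(p$genomes[[i]]), p$genomes[[i]])
    truth <- p$truth[[i]]$ssrs[order(p$truth[[i]]$ssrs$start), ]
    mapped <- ifelse(truth$location == "intergenic", "Intergenic region",
                     ifelse(truth$location == "control_region",
                            "Control region", truth$location))
    expect_equal(recs$location, mapped)
  }
})
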