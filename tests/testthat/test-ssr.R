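test_that("a TAT x6 run is one trinucleotide record of 18 bp", {
  set.seed(1)
  s <- with_clean_flanks(strrep("TAT", 6))
  recs <- scan_ssrs(s)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$motif, "TAT")
  expect_equal(recs$n_units, 6)
  expect_equal(recs$size, 18)
  expect_equal(recs$end - recs$start + 1, 18)
})

test_that("thresholds are unit-exact at the boundary", {
  set.seed(2)
  expect_equal(nrow(scan_ssrs(with_clean_flanks(strrep("A", 11), n = 30))), 0)
  r <- scan_ssrs(with_clean_flanks(strrep("A", 12), n = 30))
  expect_equal(r$n_units, 12)
  expect_equal(nchar(r$motif), 1)
})

test_that("trailing partial units are excluded from count and size", {
  set.seed(3)
  r <- scan_ssrs(with_clean_flanks(paste0(strrep("AATG", 3), "AA"), n = 30))
  expect_equal(r$n_units, 3)
  expect_equal(r$size, 12)
})

test_that("repeats are reported at their primitive period only", {
  # ATATATATATAT: period 2 (6 units), never period 4 or 6
  set.seed(4)
  r <- scan_ssrs(with_clean_flanks(strrep("AT", 6), n = 30))
  expect_equal(nrow(r), 1)
  expect_equal(r$motif, "AT")
  expect_equal(r$n_units, 6)
  # 5 units of AT fail the dinucleotide threshold and must not reappear
  # as ATAT or ATATAT
  expect_equal(nrow(scan_ssrs(with_clean_flanks(strrep("AT", 5), n = 30))), 0)
})

test_that("N breaks repeat runs and invalid characters error", {
  s <- paste0(strrep("TA", 4), "N", strrep("TA", 4))
  expect_equal(nrow(scan_ssrs(s)), 0)
  expect_error(scan_ssrs("ACGTX"), "invalid characters")
  expect_equal(nrow(scan_ssrs("")), 0)
})

test_that("scanner equals the brute-force all-substrings oracle on random sequences", {
  set.seed(500)
  # AT-rich sampling makes threshold-passing repeats reasonably frequent
  probs <- c(A = 0.42, C = 0.1, G = 0.08, T = 0.4)
  n_with_hits <- 0
  for (i in 1:200) {
    s <- rand_seq(500, probs = probs)
    got <- scan_ssrs(s)[, c("motif", "n_units", "size", "start", "end")]
    want <- oracle_scan(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("sequence", i))
    n_with_hits <- n_with_hits + (nrow(want) > 0)
  }
  expect_gt(n_with_hits, 20)  # the comparison must actually see repeats
})

test_that("coordinates are shift-equivariant under a non-repetitive prefix", {
  set.seed(5)
  core <- paste0(with_clean_flanks(strrep("AAT", 5), n = 25),
                 with_clean_flanks(strrep("TA", 7), n = 20))
  prefix <- substr(with_clean_flanks("", n = 15), 1, 15)
  base <- scan_ssrs(core)
  shifted <- scan_ssrs(paste0(prefix, core))
  expect_equal(nrow(base), nrow(shifted))
  expect_equal(shifted$start - base$start, rep(15, nrow(base)))
  expect_equal(shifted$motif, base$motif)
})

test_that("adjacent repeats merge into compound records; gaps keep them apart", {
  set.seed(6)
  s <- with_clean_flanks(paste0(strrep("AAT", 4), strrep("TG", 6)), n = 30)
  recs <- scan_ssrs(s)
  expect_equal(nrow(recs), 2)
  merged <- merge_compound(recs)
  expect_equal(nrow(merged), 1)
  expect_true(merged$compound)
  expect_equal(merged$motif, "AAT+TG")
  expect_equal(merged$size, merged$end - merged$start + 1)

  recs2 <- scan_ssrs(
    with_clean_flanks(paste0(strrep("AAT", 4), "C", strrep("TG", 6)), n = 30))
  expect_equal(nrow(merge_compound(recs2)), 2)
  expect_false(any(merge_compound(recs2)$compound))
  # single record passes through untouched
  one <- merge_compound(recs[1, ])
  expect_equal(nrow(one), 1)
  expect_false(one$compound)
})

test_that("locations classify into gene, intergenic and control region", {
  g <- generate_genome(synthetic_spec(seed = 51, ssrs = list(
    list(motif = "AAAT", n_units = 3, location = "nad4"),
    list(motif = "TAT", n_units = 6, location = "nad6"),
    list(motif = "AATT", n_units = 3, location = "intergenic"),
    list(motif = "ATTA", n_units = 3, location = "control_region"))))
  recs <- classify_locations(scan_ssrs(g$genome), g$genome)
  truth <- g$truth$ssrs
  m <- match(recs$start, truth$start)
  expect_false(anyNA(m))
  expect_equal(recs$location[recs$start == truth$start[truth$location == "nad4"]],
               "nad4")
  expect_equal(recs$location[recs$start == truth$start[truth$location == "intergenic"]],
               "Intergenic region")
  expect_equal(recs$location[recs$start == truth$start[truth$location == "control_region"]],
               "Control region")
  expect_equal(attr(recs, "coding_fraction"), 0.5)
})

test_that("relative abundance and density follow their definitions", {
  recs <- data.frame(motif = c("AAAT", "TAT", "AATT"),
                     n_units = c(3, 6, 3), size = c(12, 18, 12),
                     start = c(100, 500, 900), end = c(111, 517, 911),
                     location = NA, compound = FALSE)
  st <- ssr_stats(recs, 17197)
  expect_equal(round(st$RA, 2), 0.17)
  expect_equal(st$RA, 3 / 17.197, tolerance = 1e-12)
  expect_equal(st$RD, 42 / 17.197, tolerance = 1e-12)
  expect_equal(round(st$RD, 2), 2.44)
  expect_equal(st$at_only_fraction, 1)
  expect_equal(unname(st$class_counts[["tri"]]), 1L)
  expect_equal(sum(st$class_pct), 100)

  empty <- ssr_stats(recs[0, ], 17197)
  expect_equal(empty$RA, 0)
  expect_equal(empty$RD, 0)
})

test_that("RA and RD are recomputable from the record list alone", {
  set.seed(61)
  s <- paste0(rand_seq(3000), strrep("ATTA", 4), rand_seq(3000))
  recs <- scan_ssrs(s)
  st <- ssr_stats(recs, nchar(s))
  expect_equal(st$RA, nrow(recs) / (nchar(s) / 1000))
  expect_equal(st$RD, sum(recs$size) / (nchar(s) / 1000))
})

test_that("identical genomes give an undefined count-size correlation", {
  g <- generate_genome(synthetic_spec(seed = 71, ssrs = list(
    list(motif = "TAT", n_units = 6, location = "nad6"))))
  recs <- scan_ssrs(g$genome)
  sm <- cross_species_summary(list(g$genome, g$genome, g$genome),
                              list(recs, recs, recs))
  expect_true(is.na(sm$r_squared))
  expect_warning(cross_species_summary(list(g$genome), list(recs)),
                 "fewer than 3")
})

test_that("panel r-squared matches an independent closed-form computation", {
  p <- suppressWarnings(generate_panel(12, seed = 202))
  recs <- lapply(p$genomes, scan_ssrs)
  sm <- cross_species_summary(p$genomes, recs)
  n <- vapply(recs, nrow, integer(1))
  sz <- vapply(p$genomes, function(g) g$length, numeric(1))
  r2_closed <- (sum((n - mean(n)) * (sz - mean(sz))))^2 /
    (sum((n - mean(n))^2) * sum((sz - mean(sz))^2))
  expect_equal(sm$r_squared, r2_closed, tolerance = 1e-12)
  expect_gt(sm$r_squared, 0.25)  # slope > 0 must show through the noise
  # truth record and scanned records agree 1:1
  for (i in seq_along(recs)) {
    truth_i <- p$truth[[i]]$ssrs[order(p$truth[[i]]$ssrs$start), ]
    expect_equal(recs[[i]][, c("motif", "n_units", "start", "end")],
                 truth_i[, c("motif", "n_units", "start", "end")],
                 ignore_attr = TRUE)
  }
})
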