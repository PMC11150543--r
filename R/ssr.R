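# Perfect-microsatellite (mtSSR) scanning with MISA-style unit-count
# thresholds, location classification, and relative abundance/density.

#' Minimum unit-count thresholds for the SSR scanner
#'
#' Defaults are the MISA settings conventionally used for mitogenome scans:
#' at least 12 units for mononucleotide motifs, 6 for di-, 4 for tri-, and 3
#' for tetra-/penta-/hexanucleotide motifs, with zero tolerated interruption
#' between merged repeats.
#'
#' @param min_units named integer vector, motif length (`"1"`..`"6"`) ->
#'   minimum number of complete repeat units.
#' @param max_interruption maximum gap (bp) for compound-repeat merging.
#' @return object of class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(min_units = c(`1` = 12, `2` = 6, `3` = 4,
                                         `4` = 3, `5` = 3, `6` = 3),
                           max_interruption = 0) {
  if (!identical(sort(as.integer(names(min_units))), 1:6)) {
    stop("min_units must have keys exactly 1..6")
  }
  min_units <- as.integer(min_units[as.character(1:6)])
  if (any(min_units < 1L)) stop("all minima must be >= 1")
  structure(list(min_units = setNames(min_units, 1:6),
                 max_interruption = as.integer(max_interruption)),
            class = "ssr_thresholds")
}

# length of the shortest period of which `motif` is an integer repetition
primitive_period <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p)) {
    if (p %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), p %/% d)) return(d)
  }
  p
}

empty_ssr_frame <- function() {
  data.frame(motif = character(), n_units = integer(), size = integer(),
             start = integer(), end = integer(), location = character(),
             compound = logical(), stringsAsFactors = FALSE)
}

#' Scan a sequence for perfect tandem repeats
#'
#' Finds all maximal perfect tandem repeats with motif length 1-6 bp meeting
#' the unit-count thresholds. Every repeat is reported once, at its
#' primitive (shortest) period, as it occurs on the forward strand; only
#' complete units are counted, so a trailing partial unit is excluded from
#' `n_units` and `size`. `N` breaks any repeat run. Scanning is linear: a
#' repeat spanning the origin of a circular molecule is not detected.
#'
#' @param seq nucleotide string over `A,C,G,T,N` (or a [mito_genome()]).
#' @param thresholds an [ssr_thresholds()] object.
#' @return data.frame with columns `motif`, `n_units`, `size`, `start`,
#'   `end` (1-based inclusive), `location` (NA until
#'   [classify_locations()]), `compound` (FALSE), sorted by start.
#' @export
scan_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  if (inherits(seq, "mito_genome")) seq <- seq$sequence
  seq <- toupper(seq)
  if (!nchar(seq)) return(empty_ssr_frame())
  if (nchar(gsub("[ACGTN]", "", seq)) > 0L) {
    stop("invalid characters in sequence (allowed: A, C, G, T, N)")
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  recs <- list()
  thr <- thresholds$min_units
  for (p in 1:6) {
    if (n < p * (thr[[p]])) next
    a <- ch[seq_len(n - p)]
    b <- ch[seq_len(n - p) + p]
    m <- a == b & a != "N" & b != "N"
    r <- rle(m)
    starts <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      i <- starts[j]
      units <- (r$lengths[j] + p) %/% p
      if (units < thr[[p]]) next
      motif <- substr(seq, i, i + p - 1L)
      if (primitive_period(motif) < p) next   # reported at the shorter period
      recs[[length(recs) + 1L]] <-
        data.frame(motif = motif, n_units = units, size = units * p,
                   start = i, end = i + units * p - 1L,
                   location = NA_character_, compound = FALSE,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty_ssr_frame())
  out <- do.call(rbind, recs)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end", "motif")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent repeats into compound records
#'
#' Repeats separated by at most `max_interruption` bp (default 0: directly
#' adjacent) are merged into one compound record spanning both; component
#' motifs are retained, joined with `+`, and unit counts summed.
#'
#' @param records data.frame from [scan_ssrs()], sorted by start.
#' @param max_interruption maximum gap in bp.
#' @return data.frame of the same shape; merged rows carry `compound = TRUE`.
#' @export
merge_compound <- function(records, max_interruption = 0) {
  if (!nrow(records)) return(records)
  records <- records[order(records$start), , drop = FALSE]
  out <- records[1, , drop = FALSE]
  for (i in seq_len(nrow(records))[-1]) {
    gap <- records$start[i] - out$end[nrow(out)] - 1L
    if (gap <= max_interruption) {
      k <- nrow(out)
      out$motif[k] <- paste(out$motif[k], records$motif[i], sep = "+")
      out$n_units[k] <- out$n_units[k] + records$n_units[i]
      out$end[k] <- max(out$end[k], records$end[i])
      out$size[k] <- out$end[k] - out$start[k] + 1L
      out$compound[k] <- TRUE
    } else {
      out <- rbind(out, records[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign a genomic location to each SSR record
#'
#' The location is the name of the gene (CDS, rRNA, tRNA or pseudogene
#' feature) whose span contains the repeat's start position; otherwise
#' `"Control region"` when the start lies in the annotated control region,
#' else `"Intergenic region"`.
#'
#' @param records data.frame from [scan_ssrs()].
#' @param genome a [mito_genome()] providing the annotation.
#' @return `records` with the `location` column filled and attribute
#'   `coding_fraction` (fraction of records inside CDS/rRNA/tRNA genes).
#' @export
classify_locations <- function(records, genome) {
  stopifnot(inherits(genome, "mito_genome"))
  if (!nrow(records)) {
    attr(records, "coding_fraction") <- NA_real_
    return(records)
  }
  fx <- genome$features
  in_feature <- function(pos, i) {
    if (fx$start[i] <= fx$end[i]) {
      pos >= fx$start[i] & pos <= fx$end[i]
    } else {
      pos >= fx$start[i] | pos <= fx$end[i]   # origin-wrapping
    }
  }
  coding <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    pos <- records$start[r]
    loc <- "Intergenic region"
    for (i in seq_len(nrow(fx))) {
      if (in_feature(pos, i)) {
        if (fx$kind[i] %in% c("CDS", "rRNA", "tRNA", "pseudogene")) {
          loc <- fx$name[i]
          coding[r] <- fx$kind[i] != "pseudogene"
          break
        } else if (fx$kind[i] == "control_region") {
          loc <- "Control region"
        }
      }
    }
    records$location[r] <- loc
  }
  attr(records, "coding_fraction") <- mean(coding)
  records
}

#' Relative abundance and density of SSRs in one genome
#'
#' RA is the number of SSRs per kb of genome; RD is the number of SSR bases
#' per kb of genome. GC% is computed over the repeat nucleotides.
#'
#' @param records data.frame from [scan_ssrs()] (non-compound records).
#' @param genome_size genome length in bp.
#' @return list of class `ssr_stats`: `n_ssrs`, `genome_size`, `RA`, `RD`
#'   (full precision; conventionally reported to 2 decimals), `gc_pct`,
#'   `class_counts` and `class_pct` (mono..hexa by primitive motif length),
#'   `at_only_fraction`.
#' @export
ssr_stats <- function(records, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  kb <- genome_size / 1000
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  if (!nrow(records)) {
    return(structure(list(n_ssrs = 0L, genome_size = genome_size,
                          RA = 0, RD = 0, gc_pct = NA_real_,
                          class_counts = setNames(integer(6), classes),
                          class_pct = setNames(rep(NA_real_, 6), classes),
                          at_only_fraction = NA_real_),
                     class = "ssr_stats"))
  }
  plens <- nchar(records$motif)
  gc_bases <- sum(records$size *
                    vapply(records$motif, function(m) {
                      b <- count_bases(m)
                      (b[["G"]] + b[["C"]]) / nchar(m)
                    }, numeric(1)))
  cls <- table(factor(classes[plens], levels = classes))
  structure(list(n_ssrs = nrow(records), genome_size = genome_size,
                 RA = nrow(records) / kb,
                 RD = sum(records$size) / kb,
                 gc_pct = 100 * gc_bases / sum(records$size),
                 class_counts = cls,
                 class_pct = 100 * as.numeric(cls) / nrow(records),
                 at_only_fraction = mean(!grepl("[GC]", records$motif))),
            class = "ssr_stats")
}

#' @export
print.ssr_stats <- function(x, ...) {
  cat(sprintf("<ssr_stats> %d SSRs in %s bp: RA=%.2f /kb, RD=%.2f bp/kb, GC=%.1f%%\n",
              x$n_ssrs, format(x$genome_size, big.mark = ","),
              x$RA, x$RD, x$gc_pct))
  invisible(x)
}

#' Multi-genome SSR summary
#'
#' Per-species RA/RD/GC%, pooled motif-class percentages, the AT-only motif
#' fraction, and the Pearson correlation between SSR count and genome size
#' (r-squared and two-sided p; needs at least 3 genomes, skipped with a
#' warning otherwise, and reported as NA under zero variance).
#'
#' @param genomes list of [mito_genome()] objects (or named genome sizes).
#' @param records_list list of record data.frames, parallel to `genomes`.
#' @return list of class `ssr_panel_summary`: `per_species` data.frame,
#'   `pooled_class_pct`, `at_only_fraction`, `r_squared`, `p_value`,
#'   `n_species`.
#' @export
cross_species_summary <- function(genomes, records_list) {
  stopifnot(length(genomes) == length(records_list))
  sizes <- vapply(genomes, function(g) {
    if (inherits(g, "mito_genome")) g$length else as.numeric(g)
  }, numeric(1))
  ids <- vapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    if (inherits(g, "mito_genome")) g$identifier else
      if (!is.null(names(genomes))) names(genomes)[i] else paste0("g", i)
  }, character(1))
  per <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    st <- ssr_stats(records_list[[i]], sizes[i])
    data.frame(species = ids[i], genome_size = sizes[i], n_ssrs = st$n_ssrs,
               RA = st$RA, RD = st$RD, gc_pct = st$gc_pct,
               stringsAsFactors = FALSE)
  }))
  pooled <- do.call(rbind, records_list)
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  pooled_pct <- if (nrow(pooled)) {
    100 * as.numeric(table(factor(classes[nchar(pooled$motif)],
                                  levels = classes))) / nrow(pooled)
  } else rep(NA_real_, 6)
  at_only <- if (nrow(pooled)) mean(!grepl("[GC]", pooled$motif)) else NA_real_
  r2 <- p <- NA_real_
  if (length(genomes) < 3L) {
    warning("fewer than 3 genomes: correlation omitted")
  } else if (stats::var(per$n_ssrs) > 0 && stats::var(per$genome_size) > 0) {
    ct <- stats::cor.test(per$n_ssrs, per$genome_size)
    r2 <- unname(ct$estimate^2)
    p <- ct$p.value
  }
  structure(list(per_species = per,
                 pooled_class_pct = setNames(pooled_pct, classes),
                 at_only_fraction = at_only,
                 r_squared = r2, p_value = p,
                 n_species = length(genomes)),
            class = "ssr_panel_summary")
}

#' @export
print.ssr_panel_summary <- function(x, ...) {
  cat(sprintf("<ssr_panel_summary> %d species, %d SSRs pooled\n",
              x$n_species, sum(x$per_species$n_ssrs)))
  cat("  class %:", paste(sprintf("%s %.1f", names(x$pooled_class_pct),
                                  x$pooled_class_pct), collapse = ", "), "\n")
  if (!is.na(x$r_squared)) {
    cat(sprintf("  count ~ size: r^2 = %.2f, p = %.3g\n", x$r_squared, x$p_value))
  }
  invisible(x)
}

#' Write SSR records as a TSV table
#'
#' @param records record data.frame (optionally with a `species` column
#'   prepended by the caller).
#' @param path output file.
#' @param species optional species label column.
#' @return invisibly, `path`.
#' @export
write_ssr_records <- function(records, path, species = NULL) {
  y <- records
  if (!is.null(species)) y <- cbind(species = species, y)
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
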