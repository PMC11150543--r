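# Nucleotide composition and strand-skew statistics.
#
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C), computed on
# counts of the supplied strand. N bases are excluded from all denominators.

count_bases <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"),
    N = sum(ch == "N"))
}

#' Nucleotide composition and AT/GC skews of a sequence
#'
#' Computes per-base percentages, AT/GC/GT content and the two strand-skew
#' statistics on the sequence as given (the sense strand for a full genome,
#' the reading direction for extracted genes). `N` bases are counted but
#' excluded from every percentage and skew denominator.
#'
#' @param seq nucleotide string over `A,C,G,T,N`.
#' @param label partition label carried into the output row.
#' @return An object of class `base_stats`: a one-row data.frame with
#'   columns `partition`, `size` (bp incl. N), `pct_T`, `pct_C`, `pct_A`,
#'   `pct_G`, `at_pct`, `gc_pct`, `gt_pct` (percentages, full precision),
#'   `at_skew`, `gc_skew`, and `n_N`. Skews are `NA` (with a warning) when
#'   their denominator is zero.
#' @export
base_composition <- function(seq, label = "sequence") {
  if (!nchar(seq)) stop("empty sequence")
  n <- count_bases(seq)
  if (n[["N"]] > 0) {
    message("excluding ", n[["N"]], " N base(s) from composition denominators")
  }
  tot <- sum(n[c("A", "C", "G", "T")])
  if (tot == 0) stop("empty sequence after removing N")
  pct <- 100 * n[c("A", "C", "G", "T")] / tot
  at <- n[["A"]] + n[["T"]]
  gc <- n[["G"]] + n[["C"]]
  at_skew <- if (at > 0) (n[["A"]] - n[["T"]]) / at else {
    warning("A + T = 0: AT skew undefined"); NA_real_
  }
  gc_skew <- if (gc > 0) (n[["G"]] - n[["C"]]) / gc else {
    warning("G + C = 0: GC skew undefined"); NA_real_
  }
  out <- data.frame(partition = label, size = unname(sum(n)),
                    pct_T = pct[["T"]], pct_C = pct[["C"]],
                    pct_A = pct[["A"]], pct_G = pct[["G"]],
                    at_pct = 100 * at / tot, gc_pct = 100 * gc / tot,
                    gt_pct = pct[["G"]] + pct[["T"]],
                    at_skew = at_skew, gc_skew = gc_skew,
                    n_N = unname(n[["N"]]), stringsAsFactors = FALSE)
  class(out) <- c("base_stats", "data.frame")
  out
}

#' Composition table across the standard mitogenome partitions
#'
#' One [base_composition()] row per partition: full genome, concatenated
#' PCGs, tRNAs, rRNAs, and the two rRNA genes individually. Partitions
#' absent from the genome are skipped with a warning. The full genome is
#' measured on the deposited (sense) strand; gene partitions on
#' reading-direction sequences.
#'
#' @param genome a [mito_genome()].
#' @return A `base_stats` data.frame, one row per available partition.
#' @export
partition_table <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  wanted <- list(
    c("Full genome", "full"), c("PCGs", "PCG"), c("tRNAs", "tRNA"),
    c("rRNAs", "rRNA"), c("rrnL", "gene:rrnL"), c("rrnS", "gene:rrnS"))
  rows <- lapply(wanted, function(w) {
    seq <- tryCatch(extract_partition(genome, w[2]), error = function(e) NULL)
    if (is.null(seq)) {
      warning("partition '", w[1], "' absent; skipped")
      return(NULL)
    }
    base_composition(seq, label = w[1])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("base_stats", "data.frame")
  out
}

#' @export
print.base_stats <- function(x, digits_pct = 1, digits_skew = 3, ...) {
  y <- as.data.frame(x)
  for (col in intersect(c("pct_T", "pct_C", "pct_A", "pct_G", "at_pct",
                          "gc_pct", "gt_pct"), names(y))) {
    y[[col]] <- round_half_up(y[[col]], digits_pct)
  }
  for (col in intersect(c("at_skew", "gc_skew"), names(y))) {
    y[[col]] <- round_half_up(y[[col]], digits_skew)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# round half away from zero, as printed composition tables do
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a composition table as TSV (rounded) or JSON (full precision)
#'
#' @param stats a `base_stats` data.frame from [partition_table()].
#' @param path output file.
#' @param format `"tsv"` (percentages to 1 decimal, skews to 3) or `"json"`
#'   (full precision).
#' @return invisibly, `path`.
#' @export
write_composition <- function(stats, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(stats), path, digits = NA, pretty = TRUE)
  } else {
    y <- as.data.frame(stats)
    for (col in c("pct_T", "pct_C", "pct_A", "pct_G", "at_pct", "gc_pct", "gt_pct")) {
      y[[col]] <- round_half_up(y[[col]], 1)
    }
    for (col in c("at_skew", "gc_skew")) y[[col]] <- round_half_up(y[[col]], 3)
    write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
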