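# Codon counting and relative synonymous codon usage (RSCU) under the
# invertebrate mitochondrial genetic code (translation table 5) by default.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' Fetch a genetic code table
#'
#' @param code NCBI translation table id: 1 (standard), 2 (vertebrate
#'   mitochondrial), 4 (mold/protozoan mitochondrial) or 5 (invertebrate
#'   mitochondrial, the default throughout the package: ATA = Met,
#'   TGA = Trp, AGA/AGG = Ser).
#' @return named character vector codon -> amino acid (`*` for stops).
#' @export
genetic_code <- function(code = 5) {
  code <- as.character(code)
  if (!code %in% c("1", "2", "4", "5")) {
    stop("supported genetic codes: 1, 2, 4, 5")
  }
  Biostrings::getGeneticCode(code)
}

# synonymous-family label: Leu and Ser are split into their two codon
# families (Leu1 = CTN, Leu2 = TTR; Ser1 = AGN, Ser2 = TCN)
family_label <- function(codon, gc) {
  aa <- gc[[codon]]
  if (aa == "*") return("*")
  if (aa == "L") return(if (substr(codon, 1, 2) == "CT") "Leu1" else "Leu2")
  if (aa == "S") return(if (substr(codon, 1, 2) == "TC") "Ser2" else "Ser1")
  aa
}

codon_families <- function(gc) {
  vapply(ALL_CODONS, family_label, character(1), gc = gc)
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# drop a trailing partial codon (incomplete stop), returning the in-frame part
trim_to_frame <- function(cds) {
  n <- nchar(cds)
  substr(cds, 1L, n - n %% 3L)
}

#' Count codons across a set of coding sequences
#'
#' @param cds_list list/vector of in-frame nucleotide strings (lengths
#'   divisible by 3; apply the incomplete-stop policy first, e.g. via
#'   [cds_sequences()]). Names, if present, identify genes in error messages.
#' @param code genetic code id (see [genetic_code()]).
#' @return named integer vector over all 64 codons, with attributes
#'   `n_with_N` (codons containing N, excluded from the table) and `code`.
#' @export
count_codons <- function(cds_list, code = 5) {
  if (!length(cds_list)) stop("empty CDS list")
  nm <- names(cds_list)
  counts <- setNames(integer(64), ALL_CODONS)
  n_with_N <- 0L
  for (i in seq_along(cds_list)) {
    cds <- toupper(cds_list[[i]])
    if (nchar(cds) %% 3L != 0L) {
      stop("frame violation in ",
           if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("CDS #", i),
           ": length ", nchar(cds), " not divisible by 3")
    }
    cods <- split_codons(cds)
    hasN <- grepl("N", cods, fixed = TRUE)
    n_with_N <- n_with_N + sum(hasN)
    tab <- table(factor(cods[!hasN], levels = ALL_CODONS))
    counts <- counts + as.integer(tab)
  }
  attr(counts, "n_with_N") <- n_with_N
  attr(counts, "code") <- as.character(code)
  counts
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all codons of its synonymous family were used equally:
#' `RSCU(c) = count(c) * family_size / family_total`. A codon in a family
#' with zero total usage has RSCU 0. Stop codons are tabulated separately
#' and excluded from amino-acid families and frequency denominators.
#'
#' @param counts codon count vector from [count_codons()].
#' @param code genetic code id.
#' @return An object of class `rscu_table`: list with
#'   \describe{
#'   \item{codons}{data.frame codon / aa (family label, Leu1/Leu2/Ser1/Ser2
#'     split) / count / rscu, stop codons excluded;}
#'   \item{stops}{data.frame of stop-codon counts;}
#'   \item{amino_acids}{data.frame aa / count / pct (of all non-stop
#'     codons);}
#'   \item{n_codons}{total counted codons incl. stops;}
#'   \item{preferred}{codons with RSCU > 1;}
#'   \item{n_preferred}{their number;}
#'   \item{preferred_at_fraction}{fraction of preferred codons ending in A
#'     or T;}
#'   \item{code}{genetic code id.}}
#' @export
rscu <- function(counts, code = 5) {
  gc <- genetic_code(code)
  fam <- codon_families(gc)
  is_stop <- fam == "*"
  cnt <- as.integer(counts[ALL_CODONS])
  fam_tot <- tapply(cnt[!is_stop], fam[!is_stop], sum)
  fam_size <- table(fam[!is_stop])
  vals <- numeric(64)
  for (i in which(!is_stop)) {
    tot <- fam_tot[[fam[i]]]
    vals[i] <- if (tot > 0) cnt[i] * fam_size[[fam[i]]] / tot else 0
  }
  codons <- data.frame(codon = ALL_CODONS[!is_stop], aa = fam[!is_stop],
                       count = cnt[!is_stop], rscu = vals[!is_stop],
                       stringsAsFactors = FALSE)
  stops <- data.frame(codon = ALL_CODONS[is_stop], count = cnt[is_stop],
                      stringsAsFactors = FALSE)
  aa_tot <- sum(codons$count)
  aa_tab <- aggregate(count ~ aa, data = codons, FUN = sum)
  aa_tab$pct <- if (aa_tot > 0) 100 * aa_tab$count / aa_tot else 0
  pref <- codons$codon[codons$rscu > 1]
  at_frac <- if (length(pref)) {
    mean(substr(pref, 3, 3) %in% c("A", "T"))
  } else NA_real_
  structure(list(codons = codons, stops = stops, amino_acids = aa_tab,
                 n_codons = sum(cnt), preferred = pref,
                 n_preferred = length(pref),
                 preferred_at_fraction = at_frac,
                 code = as.character(code)),
            class = "rscu_table")
}

#' @export
print.rscu_table <- function(x, ...) {
  cat(sprintf("<rscu_table> %d codons (code %s); %d preferred (RSCU > 1), %.1f%% A/T-ending\n",
              x$n_codons, x$code, x$n_preferred,
              100 * x$preferred_at_fraction))
  top <- x$codons[order(-x$codons$rscu), ][1:5, ]
  cat("  top RSCU:",
      paste(sprintf("%s(%s)=%.2f", top$codon, top$aa, top$rscu), collapse = ", "),
      "\n")
  invisible(x)
}

#' Start and stop codon summary per gene
#'
#' The initiation codon is the first triplet; the termination codon is the
#' last complete triplet, or the recorded incomplete stop (reported padded
#' with `-`, e.g. `TA-`) when the annotated CDS length is not divisible
#' by 3. ATA/ATT/ATG starts are grouped under the `ATD` label, as is
#' conventional for insect mitogenomes.
#'
#' @param cds_list named list of CDS nucleotide strings (raw annotated
#'   spans; incomplete stops allowed).
#' @param code genetic code id (kept for interface symmetry; tallies are
#'   code-independent).
#' @return list with `per_gene` (data.frame gene/start/stop), `start_groups`
#'   (named count vector with ATD grouping) and `stop_counts`.
#' @export
start_stop_summary <- function(cds_list, code = 5) {
  if (!length(cds_list)) stop("empty CDS list")
  nm <- names(cds_list)
  if (is.null(nm)) nm <- paste0("gene", seq_along(cds_list))
  rows <- lapply(seq_along(cds_list), function(i) {
    cds <- toupper(cds_list[[i]])
    n <- nchar(cds)
    start <- substr(cds, 1, 3)
    rem <- n %% 3L
    stop_c <- if (rem == 0L) {
      substr(cds, n - 2L, n)
    } else {
      paste0(substr(cds, n - rem + 1L, n), strrep("-", 3L - rem))
    }
    data.frame(gene = nm[i], start = start, stop = stop_c,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  grp <- ifelse(per_gene$start %in% c("ATA", "ATT", "ATG"), "ATD",
                per_gene$start)
  list(per_gene = per_gene,
       start_groups = sort(table(grp), decreasing = TRUE),
       stop_counts = sort(table(per_gene$stop), decreasing = TRUE))
}

#' Extract reading-direction CDS sequences from a genome
#'
#' Convenience wrapper: one in-frame sequence per CDS feature (pseudogenes
#' excluded), oriented 5'->3'. With `trim = TRUE` a trailing partial codon
#' (incomplete stop) is dropped so every sequence is usable for codon-level
#' analyses; the annotated span is untouched for composition work.
#'
#' @param genome a [mito_genome()].
#' @param trim drop trailing partial codons?
#' @return named list of nucleotide strings.
#' @export
cds_sequences <- function(genome, trim = TRUE) {
  stopifnot(inherits(genome, "mito_genome"))
  fx <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  if (!nrow(fx)) stop("genome has no CDS features")
  out <- lapply(seq_len(nrow(fx)), function(i) {
    s <- seq_slice(genome, fx$start[i], fx$end[i])
    if (fx$strand[i] == "-") s <- revcomp(s)
    if (trim) trim_to_frame(s) else s
  })
  names(out) <- fx$name
  out
}

#' Write RSCU and amino-acid tables as TSV
#'
#' @param x an `rscu_table`.
#' @param codon_path,aa_path output TSV paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_rscu <- function(x, codon_path = NULL, aa_path = NULL) {
  stopifnot(inherits(x, "rscu_table"))
  if (!is.null(codon_path)) {
    y <- x$codons
    y$rscu <- round_half_up(y$rscu, 2)
    write.table(y, codon_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(aa_path)) {
    y <- x$amino_acids
    y$pct <- round_half_up(y$pct, 1)
    write.table(y, aa_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(codon_path, aa_path))
}
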