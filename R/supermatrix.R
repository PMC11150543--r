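# Concatenated PCG supermatrix construction and export, with per-gene
# charset coordinates for downstream tree inference in external tools.

#' Default concatenation order of the 13 mitochondrial PCGs
#'
#' @return character vector of canonical gene names.
#' @export
default_gene_order <- function() {
  c("nad1", "nad4", "nad3", "cox3", "cox1", "nad4l", "cytb",
    "atp8", "nad6", "nad2", "cox2", "atp6", "nad5")
}

translate_aligned <- function(seq, gc) {
  cods <- split_codons(seq)
  vapply(cods, function(cd) {
    if (grepl("-", cd, fixed = TRUE) || grepl("N", cd, fixed = TRUE)) return("-")
    aa <- gc[[cd]]
    if (is.na(aa)) "-" else if (aa == "*") "*" else aa
  }, character(1)) |> paste(collapse = "")
}

#' Build a concatenated multi-gene supermatrix
#'
#' Concatenates pre-aligned per-gene blocks across taxa in a configured gene
#' order, recording per-gene block coordinates (charsets) and, in nucleotide
#' mode, codon-position partition labels. In amino-acid mode each aligned
#' nucleotide block is translated (gapped codons become `-`) before
#' concatenation.
#'
#' @param alignments named list: gene -> named character vector
#'   (taxon -> aligned sequence; equal lengths within a gene).
#' @param order genes to concatenate, in order (default:
#'   [default_gene_order()] intersected with the supplied genes). `nad4L`
#'   spelling variants are normalized.
#' @param mode `"nt"` or `"aa"`.
#' @param code genetic code id for `aa` mode.
#' @param allow_missing if TRUE, taxa missing a gene are gap-filled with a
#'   warning; default is a hard error.
#' @return object of class `supermatrix`: list with `taxa`, `matrix` (named
#'   character vector of concatenated rows), `charsets` (data.frame gene /
#'   start / end), `mode`, `codon_partitions` (nt mode: integer vector of
#'   codon positions per column).
#' @export
build_supermatrix <- function(alignments, order = NULL, mode = c("nt", "aa"),
                              code = 5, allow_missing = FALSE) {
  mode <- match.arg(mode)
  names(alignments) <- normalize_gene_name(names(alignments))
  if (is.null(order)) {
    order <- intersect(default_gene_order(), names(alignments))
  } else {
    order <- normalize_gene_name(order)
  }
  unknown <- setdiff(order, names(alignments))
  if (length(unknown)) {
    stop("unknown gene(s) in order list: ", paste(unknown, collapse = ", "))
  }
  taxa <- unique(unlist(lapply(alignments[order], names)))
  if (is.null(taxa)) stop("alignments must carry taxon names")
  gc <- if (mode == "aa") genetic_code(code) else NULL
  rows <- setNames(rep("", length(taxa)), taxa)
  charsets <- data.frame(gene = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  codon_pos <- integer()
  at <- 0L
  for (g in order) {
    aln <- alignments[[g]]
    lens <- unique(nchar(aln))
    if (length(lens) != 1L) {
      stop("length mismatch within gene '", g, "': ",
           paste(lens, collapse = ", "))
    }
    block_nt <- lens
    missing <- setdiff(taxa, names(aln))
    if (length(missing)) {
      if (!allow_missing) {
        stop("gene '", g, "' missing for taxa: ",
             paste(missing, collapse = ", "),
             " (use allow_missing = TRUE to gap-fill)")
      }
      warning("gap-filling gene '", g, "' for: ",
              paste(missing, collapse = ", "))
      aln <- c(aln, setNames(rep(strrep("-", block_nt), length(missing)),
                             missing))
    }
    block <- if (mode == "aa") {
      vapply(aln[taxa], translate_aligned, character(1), gc = gc)
    } else {
      vapply(aln[taxa], toupper, character(1))
    }
    blen <- unique(nchar(block))
    rows[taxa] <- paste0(rows[taxa], block)
    charsets <- rbind(charsets,
                      data.frame(gene = g, start = at + 1L, end = at + blen,
                                 stringsAsFactors = FALSE))
    if (mode == "nt") codon_pos <- c(codon_pos, rep_len(1:3, blen))
    at <- at + blen
  }
  structure(list(taxa = taxa, matrix = rows, charsets = charsets,
                 mode = mode,
                 codon_partitions = if (mode == "nt") codon_pos else NULL),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d %s columns, %d gene blocks\n",
              length(x$taxa), nchar(x$matrix[[1]]),
              if (x$mode == "nt") "nucleotide" else "amino-acid",
              nrow(x$charsets)))
  invisible(x)
}

#' Write a supermatrix to FASTA, relaxed PHYLIP or NEXUS
#'
#' The NEXUS output includes a `sets` block with one charset per gene;
#' PHYLIP output is relaxed (whole taxon names, space-delimited). A
#' write-then-[read_matrix()] round trip reproduces the matrix.
#'
#' @param bundle a `supermatrix`.
#' @param path output file.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(bundle, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!length(bundle$taxa)) stop("empty supermatrix")
  if (anyDuplicated(bundle$taxa)) stop("duplicate taxon names")
  m <- bundle$matrix
  ncol <- nchar(m[[1]])
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", bundle$taxa), unname(m[bundle$taxa]))),
    phylip = c(sprintf("%d %d", length(bundle$taxa), ncol),
               sprintf("%s  %s", bundle$taxa, unname(m[bundle$taxa]))),
    nexus = {
      dt <- if (bundle$mode == "aa") "protein" else "dna"
      c("#NEXUS", "begin data;",
        sprintf("  dimensions ntax=%d nchar=%d;", length(bundle$taxa), ncol),
        sprintf("  format datatype=%s missing=? gap=-;", dt),
        "  matrix",
        sprintf("    %s  %s", bundle$taxa, unname(m[bundle$taxa])),
        "  ;", "end;", "begin sets;",
        sprintf("  charset %s = %d-%d;", bundle$charsets$gene,
                bundle$charsets$start, bundle$charsets$end),
        "end;")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a supermatrix written by [write_matrix()]
#'
#' @param path input file.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return named character vector taxon -> row (with attribute `charsets`
#'   for NEXUS input carrying a sets block).
#' @export
read_matrix <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    hd <- grep("^>", lines)
    out <- setNames(vapply(seq_along(hd), function(i) {
      to <- if (i < length(hd)) hd[i + 1] - 1L else length(lines)
      paste(lines[(hd[i] + 1L):to], collapse = "")
    }, character(1)), sub("^>", "", lines[hd]))
    return(out)
  }
  if (format == "phylip") {
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    parts <- strsplit(trimws(body), "\\s+")
    return(setNames(vapply(parts, `[`, "", 2L),
                    vapply(parts, `[`, "", 1L)))
  }
  # nexus
  mstart <- grep("^\\s*matrix\\s*$", lines, ignore.case = TRUE)[1]
  mend <- mstart + match(";", trimws(lines[(mstart + 1L):length(lines)])) - 1L
  body <- trimws(lines[(mstart + 1L):mend])
  body <- body[nzchar(body) & body != ";"]
  parts <- strsplit(body, "\\s+")
  out <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  cs <- regmatches(lines, regexec(
    "charset\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+);", lines))
  cs <- cs[vapply(cs, length, integer(1)) == 4L]
  if (length(cs)) {
    attr(out, "charsets") <- data.frame(
      gene = vapply(cs, `[`, "", 2L),
      start = as.integer(vapply(cs, `[`, "", 3L)),
      end = as.integer(vapply(cs, `[`, "", 4L)), stringsAsFactors = FALSE)
  }
  out
}

#' Write a RAxML-style partition file for a supermatrix
#'
#' One `DNA, gene = start-end` (or `WAG, ...` for amino acids) line per
#' gene block.
#'
#' @param bundle a `supermatrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_partitions <- function(bundle, path) {
  tag <- if (bundle$mode == "nt") "DNA" else "WAG"
  writeLines(sprintf("%s, %s = %d-%d", tag, bundle$charsets$gene,
                     bundle$charsets$start, bundle$charsets$end), path)
  invisible(path)
}
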