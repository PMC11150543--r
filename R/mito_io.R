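#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames
NULL

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "control_region", "pseudogene", "intergenic")

PCG_NAMES <- c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
               "cox1", "cox2", "cox3", "atp6", "atp8", "cytb")

TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ", "trnG",
                "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM", "trnF",
                "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY", "trnV")

RRNA_NAMES <- c("rrnL", "rrnS")

#' Construct an annotated mitochondrial genome object
#'
#' `mito_genome()` is the universal container consumed by every analysis in
#' the package: a (usually circular) nucleotide sequence plus an ordered table
#' of typed, stranded features.
#'
#' @param identifier accession or name.
#' @param sequence nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param features data.frame with columns `name`, `kind`, `start`, `end`,
#'   `strand`. Coordinates are 1-based inclusive; `kind` must be one of
#'   `CDS`, `tRNA`, `rRNA`, `control_region`, `pseudogene`, `intergenic`;
#'   `strand` is `+` or `-`. A feature may wrap the origin (`start > end`)
#'   only when `circular = TRUE`.
#' @param circular logical; is the molecule circular?
#'
#' @return An object of class `mito_genome`: a list with elements
#'   `identifier`, `sequence`, `length`, `circular` and `features` (sorted by
#'   start coordinate).
#' @export
mito_genome <- function(identifier, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("empty sequence")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("sequence contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         " (ambiguity codes other than N are rejected)")
  }
  len <- nchar(sequence)
  if (is.null(features)) {
    features <- data.frame(name = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "kind", "start", "end", "strand")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind(s): ",
           paste(setdiff(unique(features$kind), FEATURE_KINDS), collapse = ", "))
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(features$start < 1L | features$start > len |
            features$end < 1L | features$end > len)) {
      stop("feature interval outside sequence bounds [1, ", len, "]")
    }
    wraps <- features$start > features$end
    if (any(wraps) && !circular) {
      stop("origin-wrapping feature on a non-circular genome: ",
           paste(features$name[wraps], collapse = ", "))
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(identifier = as.character(identifier), sequence = sequence,
                 length = len, circular = isTRUE(circular),
                 features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s, %d features\n",
              x$identifier, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(factor(x$features$kind, levels = FEATURE_KINDS))
    tab <- tab[tab > 0]
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.mito_genome <- function(x) x$length

# reverse complement on plain character strings (N self-complementary)
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

seq_slice <- function(genome, start, end) {
  if (start <= end) {
    substr(genome$sequence, start, end)
  } else {
    # origin-wrapping slice on a circular molecule
    paste0(substr(genome$sequence, start, genome$length),
           substr(genome$sequence, 1L, end))
  }
}

feature_length <- function(genome, start, end) {
  if (start <= end) end - start + 1L else genome$length - start + 1L + end
}

# canonical lowercase vocabulary for mitochondrial gene names ------------------

AA3_TO_1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
              glu = "E", gln = "Q", gly = "G", his = "H", ile = "I",
              leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
              ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

#' Normalize a mitochondrial gene name
#'
#' Maps the many synonyms found in GenBank records (`ND1`, `COI`, `COB`,
#' `16S ribosomal RNA`, `tRNA-Leu`, ...) onto the canonical lowercase
#' vocabulary `nad1..nad6`, `nad4l`, `cox1-3`, `atp6`, `atp8`, `cytb`,
#' `rrnL`, `rrnS` and `trnX` (with `1`/`2` suffixes for the duplicated
#' Leu/Ser tRNAs).
#'
#' @param name character vector of raw gene labels.
#' @return character vector of canonical names; labels that cannot be mapped
#'   are returned lowercased and squeezed of whitespace.
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(x) {
    raw <- x
    x <- tolower(trimws(x))
    x <- gsub("[ _]+", "-", x)
    # rRNAs
    if (grepl("^(rrnl|16s|l-rrna|large)", x) || grepl("16s", x)) return("rrnL")
    if (grepl("^(rrns|12s|s-rrna|small)", x) || grepl("12s", x)) return("rrnS")
    # protein-coding genes
    x2 <- gsub("-", "", x)
    map <- c(nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4",
             nd4l = "nad4l", nd5 = "nad5", nd6 = "nad6",
             nadh1 = "nad1", nadh2 = "nad2", nadh3 = "nad3", nadh4 = "nad4",
             nadh4l = "nad4l", nadh5 = "nad5", nadh6 = "nad6",
             coi = "cox1", coii = "cox2", coiii = "cox3",
             co1 = "cox1", co2 = "cox2", co3 = "cox3",
             cox1 = "cox1", cox2 = "cox2", cox3 = "cox3",
             cob = "cytb", cytb = "cytb", cob1 = "cytb",
             atp6 = "atp6", atp8 = "atp8",
             atpase6 = "atp6", atpase8 = "atp8")
    if (x2 %in% names(map)) return(unname(map[[x2]]))
    if (x2 %in% c(PCG_NAMES, "nad4l")) return(x2)
    # tRNAs: trnI / trn-I / tRNA-Ile / trnL1 ...
    m <- regmatches(x, regexec("^trna?-?([a-z]{3})([12])?$", x))[[1]]
    if (length(m) == 3L && m[2] %in% names(AA3_TO_1)) {
      return(paste0("trn", AA3_TO_1[[m[2]]], m[3]))
    }
    m <- regmatches(x2, regexec("^trna?([a-z])([12])?$", x2))[[1]]
    if (length(m) == 3L && toupper(m[2]) %in% AA3_TO_1) {
      return(paste0("trn", toupper(m[2]), m[3]))
    }
    gsub("\\s+", "", tolower(raw))
  }, character(1), USE.NAMES = FALSE)
}

# bare trnL/trnS are ambiguous; suffix duplicates by order of appearance
disambiguate_trna <- function(names) {
  for (base in c("trnL", "trnS")) {
    idx <- which(names == base)
    if (length(idx)) names[idx] <- paste0(base, seq_along(idx))
  }
  names
}

# GenBank flat-file reader -----------------------------------------------------

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  rng <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    n <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (any(is.na(n))) stop("cannot parse location '", p, "'")
    if (length(n) == 1L) n <- c(n, n)
    n
  })
  starts <- vapply(rng, `[`, integer(1), 1L)
  ends <- vapply(rng, `[`, integer(1), 2L)
  list(start = min(starts), end = max(ends), strand = strand)
}

parse_genbank <- function(lines, path = "<text>") {
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("format error in ", path, ": no LOCUS line (line 1)")
  circular <- grepl("circular", lines[locus_i[1]], ignore.case = TRUE)
  id_m <- regmatches(lines[locus_i[1]],
                     regexec("^LOCUS\\s+(\\S+)", lines[locus_i[1]]))[[1]]
  identifier <- if (length(id_m) == 2L) id_m[2] else "unknown"
  acc_i <- grep("^ACCESSION\\s+\\S", lines)
  if (length(acc_i)) {
    identifier <- sub("^ACCESSION\\s+(\\S+).*$", "\\1", lines[acc_i[1]])
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("format error in ", path, ": no ORIGIN block")
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("validation error in ", path, ": empty sequence")
  }

  feats <- data.frame(name = character(), kind = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  dropped <- character()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    starts <- grep("^ {1,10}\\S", block) # new feature: key in cols 6-20
    starts <- starts[grepl("^\\s{1,10}[A-Za-z'_-]+\\s+\\S", block[starts])]
    bounds <- c(starts, length(block) + 1L)
    for (k in seq_along(starts)) {
      chunk <- block[starts[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
      if (key == "source") next
      loc <- sub("^\\s*\\S+\\s+(\\S*)$", "\\1", chunk[1])
      quals <- chunk[-1]
      # continuation lines of the location (no '/')
      cont <- !grepl("^\\s+/", quals)
      if (any(cont)) {
        first_q <- match(FALSE, cont, nomatch = length(quals) + 1L)
        if (first_q > 1L) {
          loc <- paste0(loc, paste(trimws(quals[seq_len(first_q - 1L)]),
                                   collapse = ""))
          quals <- quals[-seq_len(first_q - 1L)]
        }
      }
      qual_txt <- paste(trimws(quals), collapse = " ")
      get_qual <- function(q) {
        m <- regmatches(qual_txt,
                        regexec(paste0("/", q, "=\"([^\"]*)\""), qual_txt))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      name <- get_qual("gene")
      if (is.na(name)) name <- get_qual("product")
      if (is.na(name)) name <- key
      pseudo <- grepl("/pseudo\\b", qual_txt) || grepl("pseudogene", qual_txt)
      kind <- switch(key,
        CDS = if (pseudo) "pseudogene" else "CDS",
        tRNA = "tRNA",
        rRNA = "rRNA",
        "D-loop" = "control_region",
        misc_feature = {
          note <- get_qual("note")
          if (!is.na(note) &&
              grepl("control region|A\\+T|AT-rich", note, ignore.case = TRUE)) {
            "control_region"
          } else NA_character_
        },
        NA_character_)
      if (is.na(kind)) {
        dropped <- c(dropped, key)
        next
      }
      pos <- tryCatch(parse_gb_location(loc), error = function(e) {
        stop("format error in ", path, " near feature '", key, "': ",
             conditionMessage(e))
      })
      nm <- normalize_gene_name(name)
      if (kind == "control_region") nm <- "control_region"
      feats <- rbind(feats, data.frame(name = nm, kind = kind,
                                       start = pos$start, end = pos$end,
                                       strand = pos$strand,
                                       stringsAsFactors = FALSE))
    }
  }
  if (length(dropped)) {
    warning("dropped feature(s) of unknown kind: ",
            paste(unique(dropped), collapse = ", "))
  }
  feats$name <- disambiguate_trna(feats$name)
  mito_genome(identifier, sequence, feats, circular = circular)
}

#' Read an annotated mitochondrial genome
#'
#' Supports GenBank flat files (`format = "genbank"`) and a FASTA sequence
#' with a companion tab-separated annotation table
#' (`format = "fasta+table"`; columns `name`, `kind`, `start`, `end`,
#' `strand`). Gene names are normalized via [normalize_gene_name()]; feature
#' kinds outside the supported vocabulary are dropped with a warning.
#'
#' @param path path to the GenBank or FASTA file.
#' @param format input format.
#' @param table path to the annotation TSV (required for `fasta+table`).
#' @param circular circular flag for `fasta+table` input (GenBank reads it
#'   from the LOCUS line).
#' @return A [mito_genome()] object.
#' @export
read_mito_genome <- function(path, format = c("genbank", "fasta+table"),
                             table = NULL, circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") {
    parse_genbank(readLines(path, warn = FALSE), path = path)
  } else {
    if (is.null(table)) stop("'fasta+table' requires a companion annotation table")
    if (!file.exists(table)) stop("file not found: ", table)
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("validation error in ", path, ": empty sequence")
    ann <- read.delim(table, stringsAsFactors = FALSE)
    need <- c("name", "kind", "start", "end", "strand")
    if (!all(need %in% names(ann))) {
      stop("format error in ", table, ": header must contain ",
           paste(need, collapse = "/"))
    }
    keep <- ann$kind %in% FEATURE_KINDS
    if (any(!keep)) {
      warning("dropped feature(s) of unknown kind: ",
              paste(unique(ann$kind[!keep]), collapse = ", "))
      ann <- ann[keep, , drop = FALSE]
    }
    ann$name <- disambiguate_trna(normalize_gene_name(ann$name))
    mito_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]),
                ann, circular = circular)
  }
}

#' Write a mito_genome as FASTA plus annotation table
#'
#' The inverse of `read_mito_genome(..., format = "fasta+table")`; a
#' write-then-read round trip reproduces sequence and features exactly.
#'
#' @param genome a [mito_genome()].
#' @param fasta,table output paths.
#' @return invisibly, the two paths.
#' @export
write_mito_genome <- function(genome, fasta, table) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$identifier))
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  write.table(genome$features, table, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, table = table))
}

#' Extract a sequence partition from a genome
#'
#' Concatenates the requested feature class in genome order, with
#' minus-strand features reverse-complemented so every gene contributes its
#' reading-direction (5'->3') sequence. Pseudogenes are excluded from the
#' `PCG` partition.
#'
#' @param genome a [mito_genome()].
#' @param partition one of `"full"`, `"PCG"`, `"tRNA"`, `"rRNA"`, or
#'   `"gene:<name>"` for a single gene (canonical name).
#' @return A nucleotide string.
#' @export
extract_partition <- function(genome, partition) {
  stopifnot(inherits(genome, "mito_genome"))
  if (partition == "full") return(genome$sequence)
  fx <- genome$features
  if (grepl("^gene:", partition)) {
    gname <- sub("^gene:", "", partition)
    rows <- fx[fx$name == gname, , drop = FALSE]
    if (!nrow(rows)) stop("empty partition: no feature named '", gname, "'")
  } else if (partition %in% c("PCG", "tRNA", "rRNA")) {
    kind <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")[[partition]]
    rows <- fx[fx$kind == kind, , drop = FALSE]
    if (!nrow(rows)) stop("empty partition: genome has no ", kind, " features")
  } else {
    stop("unknown partition '", partition,
         "' (use full, PCG, tRNA, rRNA or gene:<name>)")
  }
  pieces <- vapply(seq_len(nrow(rows)), function(i) {
    s <- seq_slice(genome, rows$start[i], rows$end[i])
    if (rows$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Per-feature inventory with spacers and overlaps
#'
#' One row per feature (gene, kind, strand, start, end, length) plus the
#' spacer to the next feature: `next.start - end - 1`, negative values being
#' overlaps of that many bp.
#'
#' @param genome a [mito_genome()].
#' @return data.frame with columns `name`, `kind`, `strand`, `start`, `end`,
#'   `length`, `spacer_to_next` (NA for the last feature); attributes
#'   `kind_counts` (named vector) and `identifier`.
#' @export
inventory_report <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  fx <- genome$features
  if (!nrow(fx)) stop("genome has no features")
  len <- vapply(seq_len(nrow(fx)),
                function(i) feature_length(genome, fx$start[i], fx$end[i]),
                integer(1))
  spacer <- c(fx$start[-1] - fx$end[-nrow(fx)] - 1L, NA_integer_)
  out <- data.frame(name = fx$name, kind = fx$kind, strand = fx$strand,
                    start = fx$start, end = fx$end, length = len,
                    spacer_to_next = spacer, stringsAsFactors = FALSE)
  attr(out, "kind_counts") <- table(factor(fx$kind, levels = FEATURE_KINDS))
  attr(out, "identifier") <- genome$identifier
  out
}

#' Gene inventory and missing-gene report
#'
#' Compares the genome's gene content against the canonical insect
#' mitochondrial inventory (13 protein-coding genes, 22 tRNAs, 2 rRNAs; 37
#' genes in total).
#'
#' @param genome a [mito_genome()].
#' @return list with `n_genes` (CDS + tRNA + rRNA features), `present`,
#'   `missing` (canonical genes absent from the record).
#' @export
gene_inventory <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  fx <- genome$features
  genes <- fx$name[fx$kind %in% c("CDS", "tRNA", "rRNA")]
  canonical <- c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES)
  list(n_genes = length(genes),
       present = genes,
       missing = setdiff(canonical, genes))
}
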