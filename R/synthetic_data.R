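# Seeded generator of annotated synthetic mitogenomes with full ground-truth
# records, so every pipeline stage can be validated without real accessions.
#
# The generated genome emulates a pentatomid-like insect mitogenome: a
# circular AT-rich molecule with 13 protein-coding genes, 22 tRNAs, 2 rRNAs
# and a control region laid out in the ancestral insect gene order, with
# minus-strand genes generated in reading orientation and reverse-
# complemented into the genome. The background is scrubbed of incidental
# SSRs by local resampling, and global base counts are trimmed to the target
# composition, so that embedded repeats and composition targets are exact
# ground truth.

#' Default pentatomid-like feature layout
#'
#' 13 CDS, 22 tRNA and 2 rRNA features plus a control region in the
#' ancestral insect mitochondrial gene order, with typical gene lengths and
#' strands. `spacer_after` is the intergenic gap following each feature; one
#' larger spacer provides an intergenic region able to host repeats.
#'
#' @return data.frame with columns `name`, `kind`, `length`, `strand`,
#'   `spacer_after`.
#' @export
default_layout <- function() {
  f <- function(name, kind, length, strand, spacer = 2L) {
    data.frame(name = name, kind = kind, length = as.integer(length),
               strand = strand, spacer_after = as.integer(spacer),
               stringsAsFactors = FALSE)
  }
  rbind(
    f("trnI", "tRNA", 66, "+"), f("trnQ", "tRNA", 66, "-"),
    f("trnM", "tRNA", 66, "+"), f("nad2", "CDS", 999, "+"),
    f("trnW", "tRNA", 66, "+"), f("trnC", "tRNA", 66, "-"),
    f("trnY", "tRNA", 66, "-"), f("cox1", "CDS", 1536, "+"),
    f("trnL2", "tRNA", 66, "+"), f("cox2", "CDS", 684, "+"),
    f("trnK", "tRNA", 66, "+"), f("trnD", "tRNA", 66, "+"),
    f("atp8", "CDS", 159, "+"), f("atp6", "CDS", 672, "+"),
    f("cox3", "CDS", 789, "+"), f("trnG", "tRNA", 66, "+"),
    f("nad3", "CDS", 354, "+"), f("trnA", "tRNA", 66, "+"),
    f("trnR", "tRNA", 66, "+"), f("trnN", "tRNA", 66, "+"),
    f("trnS1", "tRNA", 66, "+"), f("trnE", "tRNA", 66, "+"),
    f("trnF", "tRNA", 66, "-"), f("nad5", "CDS", 1677, "-"),
    f("trnH", "tRNA", 66, "-"), f("nad4", "CDS", 1332, "-"),
    f("nad4l", "CDS", 264, "-"), f("trnT", "tRNA", 66, "+"),
    f("trnP", "tRNA", 66, "-"), f("nad6", "CDS", 498, "+"),
    f("cytb", "CDS", 1137, "+"), f("trnS2", "tRNA", 66, "+", 500L),
    f("nad1", "CDS", 924, "-"), f("trnL1", "tRNA", 66, "-"),
    f("rrnL", "rRNA", 1284, "-"), f("trnV", "tRNA", 66, "-"),
    f("rrnS", "rRNA", 792, "-"),
    f("control_region", "control_region", 1200, "+", 0L))
}

#' Specification for one synthetic mitogenome
#'
#' @param base_pct named numeric vector of target base percentages
#'   (`A`,`C`,`G`,`T`), summing to 100. The default reproduces an AT-rich
#'   (74% AT) pentatomid-like composition with positive AT skew and negative
#'   GC skew.
#' @param layout feature layout data.frame (see [default_layout()]); CDS
#'   lengths must be divisible by 3.
#' @param ssrs list of embedded repeats, each a list/vector with `motif`,
#'   `n_units`, and `location` (a gene name from the layout,
#'   `"intergenic"`, or `"control_region"`).
#' @param seed integer seed; a fixed seed makes the genome bit-identical.
#' @param identifier genome name.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(base_pct = c(A = 42.5, C = 15.0, G = 11.0, T = 31.5),
                           layout = default_layout(), ssrs = list(),
                           seed = 1L, identifier = "synthetic") {
  stopifnot(abs(sum(base_pct) - 100) < 1e-6,
            all(c("A", "C", "G", "T") %in% names(base_pct)))
  if (any(layout$length[layout$kind == "CDS"] %% 3L != 0L)) {
    stop("CDS lengths must be divisible by 3")
  }
  glen <- sum(layout$length) + sum(layout$spacer_after)
  structure(list(base_pct = base_pct[c("A", "C", "G", "T")], layout = layout,
                 ssrs = ssrs, seed = as.integer(seed),
                 genome_length = glen, identifier = identifier),
            class = "synthetic_spec")
}

sample_bases <- function(n, probs) {
  if (n == 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# non-stop codon sampled with per-base probabilities
NONSTOP_CACHE <- new.env(parent = emptyenv())
nonstop_codons <- function(gc) {
  key <- paste(which(gc == "*"), collapse = ",")
  if (is.null(NONSTOP_CACHE[[key]])) {
    NONSTOP_CACHE[[key]] <- names(gc)[gc != "*"]
  }
  NONSTOP_CACHE[[key]]
}

codon_probs <- function(codons, probs) {
  p <- vapply(codons, function(cd) {
    prod(probs[strsplit(cd, "")[[1]]])
  }, numeric(1))
  p / sum(p)
}

gen_cds <- function(len, probs, gc) {
  ncod <- len %/% 3L
  cods <- nonstop_codons(gc)
  cp <- codon_probs(cods, probs)
  body <- sample(cods, ncod - 2L, replace = TRUE, prob = cp)
  start <- sample(c("ATA", "ATT", "ATG", "TTG"), 1L,
                  prob = c(0.35, 0.35, 0.2, 0.1))
  paste(c(start, body, sample(c("TAA", "TAG"), 1L, prob = c(0.8, 0.2))),
        collapse = "")
}

is_valid_orf <- function(cds, gc) {
  cods <- split_codons(cds)
  k <- length(cods)
  substr(cds, 1, 3) %in% c("ATA", "ATT", "ATG", "TTG") &&
    gc[[cods[k]]] == "*" &&
    !any(gc[cods[-k]] == "*")
}

# positions covered by a span table (data.frame start/end)
span_positions <- function(spans) {
  if (is.null(spans) || !nrow(spans)) return(integer())
  unlist(lapply(seq_len(nrow(spans)),
                function(i) spans$start[i]:spans$end[i]))
}

#' Generate an annotated synthetic mitogenome with ground truth
#'
#' Builds the genome from its [synthetic_spec()]: feature sequences (CDS are
#' valid open reading frames under the chosen code), embedded SSRs at
#' recorded coordinates, incidental-repeat scrubbing by local resampling,
#' and a final composition trim that makes realized base counts match the
#' target percentages to within one base each. [scan_ssrs()] on the result
#' finds exactly the embedded repeats.
#'
#' @param spec a [synthetic_spec()].
#' @param code genetic code id for ORF construction.
#' @param thresholds [ssr_thresholds()] against which the background is
#'   scrubbed.
#' @param max_iter cap on scrub/trim iterations.
#' @return list with `genome` (a [mito_genome()]) and `truth` (list:
#'   `features`, `ssrs` data.frame with motif/n_units/size/start/end/
#'   location, `base_pct_target`, `seed`).
#' @export
generate_genome <- function(spec, code = 5, thresholds = ssr_thresholds(),
                            max_iter = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gc <- genetic_code(code)
  probs <- spec$base_pct / 100
  lay <- spec$layout

  pieces <- character(0)
  feats <- NULL
  pos <- 1L
  for (i in seq_len(nrow(lay))) {
    len <- lay$length[i]
    piece <- if (lay$kind[i] == "CDS") {
      cds <- gen_cds(len, probs, gc)
      if (lay$strand[i] == "-") revcomp(cds) else cds
    } else {
      sample_bases(len, probs)
    }
    feats <- rbind(feats, data.frame(
      name = lay$name[i], kind = lay$kind[i], start = pos,
      end = pos + len - 1L, strand = lay$strand[i], stringsAsFactors = FALSE))
    pieces <- c(pieces, piece)
    if (lay$spacer_after[i] > 0L) {
      pieces <- c(pieces, sample_bases(lay$spacer_after[i], probs))
    }
    pos <- pos + len + lay$spacer_after[i]
  }
  seqstr <- paste(pieces, collapse = "")
  stopifnot(nchar(seqstr) == spec$genome_length)

  # ---- embed the requested SSRs ------------------------------------------
  embeds <- NULL
  for (k in seq_along(spec$ssrs)) {
    ins <- spec$ssrs[[k]]
    motif <- toupper(ins$motif)
    n_units <- as.integer(ins$n_units)
    size <- nchar(motif) * n_units
    loc <- ins$location
    host <- if (loc == "intergenic") {
      # the large spacer following trnS2
      i <- which(lay$name == "trnS2")
      a <- feats$end[feats$name == "trnS2"] + 1L
      c(a, a + lay$spacer_after[i] - 1L, "intergenic")
    } else if (loc == "control_region") {
      r <- feats[feats$kind == "control_region", ]
      c(r$start, r$end, "control_region")
    } else {
      r <- feats[feats$name == loc, ]
      if (!nrow(r)) stop("embedding location '", loc, "' not in layout")
      c(r$start, r$end, r$kind)
    }
    a <- as.integer(host[1]); b <- as.integer(host[2])
    if (b - a + 1L < size + 8L) {
      stop("infeasible spec: SSR of ", size, " bp longer than host ", loc)
    }
    placed <- FALSE
    for (try in seq_len(200L)) {
      # keep 4 bp (and the start/stop codons of a CDS) clear at both ends
      margin <- if (host[3] == "CDS") 6L else 4L
      s <- sample((a + margin):(b - margin - size + 1L), 1L)
      # keep clear of previously embedded repeats (no adjacency/overlap)
      if (!is.null(embeds) &&
          any(embeds$end >= s - 3L & embeds$start <= s + size + 2L)) next
      cand <- seqstr
      substr(cand, s, s + size - 1L) <- strrep(motif, n_units)
      if (host[3] == "CDS") {
        r <- feats[feats$name == loc, ]
        cds <- substr(cand, r$start, r$end)
        if (r$strand == "-") cds <- revcomp(cds)
        if (!is_valid_orf(cds, gc)) next
      }
      seqstr <- cand
      embeds <- rbind(embeds, data.frame(
        motif = motif, n_units = n_units, size = size, start = s,
        end = s + size - 1L, location = loc, stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not embed SSR ", motif, " x", n_units, " in ", loc,
           " without breaking the reading frame")
    }
  }
  protected <- span_positions(embeds)

  # ---- scrub incidental repeats + trim composition -----------------------
  cds_rows <- feats[feats$kind == "CDS", , drop = FALSE]
  in_cds <- rep(FALSE, nchar(seqstr))
  for (i in seq_len(nrow(cds_rows))) {
    in_cds[cds_rows$start[i]:cds_rows$end[i]] <- TRUE
  }
  is_protected <- rep(FALSE, nchar(seqstr))
  is_protected[protected] <- TRUE

  resample_window <- function(seqstr, w_start, w_end) {
    # resample, ORF-safely, every unprotected position of the window
    pos <- setdiff(w_start:w_end, which(is_protected))
    if (!length(pos)) return(seqstr)
    cds_pos <- pos[in_cds[pos]]
    free_pos <- pos[!in_cds[pos]]
    for (p in free_pos) {
      substr(seqstr, p, p) <- sample(names(probs), 1L, prob = probs)
    }
    if (length(cds_pos)) {
      cods <- nonstop_codons(gc)
      cp <- codon_probs(cods, probs)
      for (i in seq_len(nrow(cds_rows))) {
        r <- cds_rows[i, ]
        hit <- cds_pos[cds_pos >= r$start & cds_pos <= r$end]
        if (!length(hit)) next
        cds <- substr(seqstr, r$start, r$end)
        if (r$strand == "-") cds <- revcomp(cds)
        # protected mask in reading orientation
        gpos_all <- if (r$strand == "-") r$end:r$start else r$start:r$end
        prot_read <- is_protected[gpos_all]
        # codon indices touched (in reading orientation)
        off <- if (r$strand == "-") r$end - hit else hit - r$start
        cidx <- unique(off %/% 3L + 1L)
        ncod <- nchar(cds) %/% 3L
        cidx <- cidx[cidx > 1L & cidx < ncod]  # never the start or stop codon
        for (ci in cidx) {
          span <- ((ci - 1L) * 3L + 1L):(ci * 3L)
          fixed <- which(prot_read[span])
          cur <- substr(cds, span[1], span[3])
          pool <- if (length(fixed)) {
            # protected bases stay; vary only the free positions
            keep <- vapply(cods, function(cd) {
              all(substring(cd, fixed, fixed) == substring(cur, fixed, fixed))
            }, logical(1))
            cods[keep]
          } else cods
          if (!length(pool)) next
          w <- cp[match(pool, cods)]
          substr(cds, span[1], span[3]) <- sample(pool, 1L, prob = w)
        }
        repl <- if (r$strand == "-") revcomp(cds) else cds
        substr(seqstr, r$start, r$end) <- repl
      }
    }
    seqstr
  }

  trim_composition <- function(seqstr) {
    n <- nchar(seqstr)
    target <- floor(probs * n)
    rem <- n - sum(target)
    frac <- probs * n - target
    target[order(-frac)[seq_len(rem)]] <- target[order(-frac)[seq_len(rem)]] + 1
    ch <- strsplit(seqstr, "")[[1]]
    eligible <- which(!in_cds & !is_protected)
    cur <- table(factor(ch, levels = c("A", "C", "G", "T")))
    delta <- as.numeric(target[c("A", "C", "G", "T")]) - as.numeric(cur)
    names(delta) <- c("A", "C", "G", "T")
    over <- names(delta)[delta < 0]
    under <- names(delta)[delta > 0]
    for (b_over in over) {
      cand <- eligible[ch[eligible] == b_over]
      need <- -delta[[b_over]]
      if (need > length(cand)) need <- length(cand)
      pick <- sample(cand, need)
      # assign deficit bases proportionally
      fills <- sample(rep(under, times = pmax(delta[under], 0))[seq_len(need)])
      ch[pick] <- fills
      delta[under] <- delta[under] - table(factor(fills, levels = under))
    }
    paste(ch, collapse = "")
  }

  matches_embed <- function(recs) {
    if (is.null(embeds)) return(rep(FALSE, nrow(recs)))
    key <- paste(recs$start, recs$end, recs$motif)
    key %in% paste(embeds$start, embeds$end, embeds$motif)
  }

  for (iter in seq_len(max_iter)) {
    recs <- scan_ssrs(seqstr, thresholds)
    incid <- recs[!matches_embed(recs), , drop = FALSE]
    if (!nrow(incid)) {
      seq2 <- trim_composition(seqstr)
      recs2 <- scan_ssrs(seq2, thresholds)
      if (!any(!matches_embed(recs2))) {
        seqstr <- seq2
        break
      }
      seqstr <- seq2 # keep trim; fix fresh repeats next iteration
    } else {
      for (i in seq_len(nrow(incid))) {
        seqstr <- resample_window(seqstr,
                                  max(1L, incid$start[i] - 1L),
                                  min(nchar(seqstr), incid$end[i] + 1L))
      }
    }
    if (iter == max_iter) {
      stop("scrub loop exceeded ", max_iter,
           " iterations; remaining incidental repeats: ",
           paste(sprintf("%s@%d-%d", incid$motif, incid$start, incid$end),
                 collapse = ", "))
    }
  }

  # ---- verify ground truth ----------------------------------------------
  final <- scan_ssrs(seqstr, thresholds)
  n_embedded <- if (is.null(embeds)) 0L else nrow(embeds)
  if (nrow(final) != n_embedded || !all(matches_embed(final))) {
    stop("generator postcondition failed: scanned repeats do not match the ",
         "embedded truth")
  }
  genome <- mito_genome(spec$identifier, seqstr, feats, circular = TRUE)
  truth <- list(features = feats,
                ssrs = if (is.null(embeds)) empty_ssr_frame()[0, 1:6] else embeds,
                base_pct_target = spec$base_pct, seed = spec$seed)
  list(genome = genome, truth = truth)
}

#' Mutate a CDS into a pair with known substitution classes
#'
#' Produces two copies of a coding sequence differing at exactly `n_syn`
#' synonymous and `n_nonsyn` nonsynonymous single-nucleotide positions, at
#' most one change per codon, never touching the start or stop codon and
#' never creating a stop. With one change per codon, NG86 pathway averaging
#' is exact, so the truth classification is unambiguous.
#'
#' @param cds in-frame coding sequence (valid ORF).
#' @param n_syn,n_nonsyn number of synonymous / nonsynonymous changes.
#' @param seed integer seed.
#' @param code genetic code id.
#' @return list with `copyA`, `copyB`, and `truth` (data.frame codon_index /
#'   position / from / to / class).
#' @export
mutate_cds_pair <- function(cds, n_syn, n_nonsyn, seed = 1L, code = 5) {
  set.seed(seed)
  gc <- genetic_code(code)
  cds <- toupper(cds)
  cods <- split_codons(cds)
  ncod <- length(cods)
  # candidate codons: internal, non-stop
  cand <- setdiff(seq_len(ncod)[-1], ncod)
  cand <- cand[gc[cods[cand]] != "*"]

  neighbors <- function(ci, synonymous) {
    cd <- cods[ci]
    aa <- gc[[cd]]
    out <- list()
    for (p in 1:3) for (b in setdiff(NUC, substr(cd, p, p))) {
      nxt <- mutate_at(cd, p, b)
      if (gc[[nxt]] == "*") next
      if ((gc[[nxt]] == aa) == synonymous) {
        out[[length(out) + 1L]] <- list(pos = p, to = b, codon = nxt)
      }
    }
    out
  }

  cand <- sample(cand)
  truth <- NULL
  newcods <- cods
  take <- function(class_syn, n_needed) {
    got <- 0L
    while (got < n_needed && length(cand)) {
      ci <- cand[1]
      cand <<- cand[-1]
      nb <- neighbors(ci, class_syn)
      if (!length(nb)) next
      ch <- nb[[sample.int(length(nb), 1L)]]
      newcods[ci] <<- ch$codon
      truth <<- rbind(truth, data.frame(
        codon_index = ci, position = (ci - 1L) * 3L + ch$pos,
        from = substr(cods[ci], ch$pos, ch$pos), to = ch$to,
        class = if (class_syn) "synonymous" else "nonsynonymous",
        stringsAsFactors = FALSE))
      got <- got + 1L
    }
    if (got < n_needed) {
      stop("infeasible request: only ", got, " of ", n_needed, " ",
           if (class_syn) "synonymous" else "nonsynonymous",
           " changes could be placed")
    }
  }
  if (n_syn > 0) take(TRUE, n_syn)
  if (n_nonsyn > 0) take(FALSE, n_nonsyn)
  list(copyA = cds, copyB = paste(newcods, collapse = ""),
       truth = if (is.null(truth)) {
         data.frame(codon_index = integer(), position = integer(),
                    from = character(), to = character(), class = character())
       } else truth[order(truth$codon_index), ])
}

#' Generate a panel of synthetic genomes with size-linked SSR counts
#'
#' Per-species SSR counts follow a stated linear model of genome size,
#' `count = intercept + slope * size + Normal(0, noise_sd)`, rounded and
#' floored at zero. Embedded motifs are AT-only with probability
#' `at_only_prob`; motif-length classes follow `class_probs`; the fraction
#' of repeats placed inside genes is `coding_fraction`. Genome sizes vary
#' through the control-region length.
#'
#' @param n_species number of genomes (>= 3).
#' @param size_range genome length range in bp.
#' @param slope,intercept,noise_sd SSR-count model (defaults give 3-20
#'   repeats over 15.9-17.5 kb, matching the spread seen in pentatomid
#'   panels).
#' @param coding_fraction fraction of embedded repeats placed inside genes.
#' @param class_probs probabilities of motif lengths 1..6.
#' @param at_only_prob probability a motif uses only A/T.
#' @param seed integer seed.
#' @return list with `genomes` (list of [mito_genome()]), `truth` (list per
#'   species: `ssrs`, `n_ssrs_model`), and `model` (the count-model
#'   parameters actually used).
#' @export
generate_panel <- function(n_species, size_range = c(15900, 17500),
                           slope = 0.005, intercept = -72, noise_sd = 1.5,
                           coding_fraction = 0.7,
                           class_probs = c(0.014, 0.06, 0.404, 0.431,
                                           0.075, 0.016),
                           at_only_prob = 0.988, seed = 1L) {
  if (n_species < 3L) stop("n_species must be >= 3")
  set.seed(seed)
  base_len <- sum(default_layout()$length) + sum(default_layout()$spacer_after)
  cr_base <- 1200L
  sizes <- round(stats::runif(n_species, size_range[1], size_range[2]))
  counts <- pmax(0L, round(intercept + slope * sizes +
                             stats::rnorm(n_species, 0, noise_sd)))
  # hosts able to take repeats without breaking a reading frame too often
  gene_hosts <- data.frame(
    name = c("nad2", "cox1", "nad5", "nad4", "nad6", "cytb", "nad1",
             "rrnL", "rrnS"),
    kind = c(rep("CDS", 7), "rRNA", "rRNA"),
    strand = c("+", "+", "-", "-", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE)
  gc5 <- genetic_code(5)
  # can `motif` repeated sit inside a CDS of this strand in some frame
  # without introducing an in-frame stop codon?
  cds_compatible <- function(motif, n_units, strand) {
    block <- strrep(motif, n_units)
    if (strand == "-") block <- revcomp(block)
    for (o in 0:2) {
      st <- seq(1L + o, nchar(block) - 2L, by = 3L)
      if (!length(st)) next
      cods <- substring(block, st, st + 2L)
      if (!any(gc5[cods] == "*")) return(TRUE)
    }
    FALSE
  }
  pick_gene_host <- function(motif, n_units) {
    ok <- vapply(seq_len(nrow(gene_hosts)), function(i) {
      gene_hosts$kind[i] == "rRNA" ||
        cds_compatible(motif, n_units, gene_hosts$strand[i])
    }, logical(1))
    sample(gene_hosts$name[ok], 1L)
  }
  mk_motif <- function(plen, at_only) {
    repeat {
      alpha <- if (at_only) c("A", "T") else c("A", "C", "G", "T")
      m <- paste(sample(alpha, plen, replace = TRUE,
                        prob = if (at_only) c(0.6, 0.4) else
                          c(0.4, 0.1, 0.1, 0.4)), collapse = "")
      if (primitive_period(m) == plen) return(m)
    }
  }
  thr <- ssr_thresholds()$min_units
  species_seed <- sample.int(2^20, n_species) + seed
  genomes <- vector("list", n_species)
  truth <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    lay <- default_layout()
    cr <- which(lay$kind == "control_region")
    lay$length[cr] <- cr_base + (sizes[i] - base_len)
    ssrs <- lapply(seq_len(counts[i]), function(j) {
      plen <- sample(1:6, 1L, prob = class_probs)
      motif <- mk_motif(plen, stats::runif(1) < at_only_prob)
      n_units <- thr[[plen]] + stats::rpois(1, 0.7)
      loc <- if (stats::runif(1) < coding_fraction) {
        pick_gene_host(motif, n_units)
      } else {
        sample(c("intergenic", "control_region"), 1L)
      }
      list(motif = motif, n_units = n_units, location = loc)
    })
    sp <- synthetic_spec(layout = lay, ssrs = ssrs, seed = species_seed[i],
                         identifier = sprintf("synth%02d", i))
    g <- generate_genome(sp)
    genomes[[i]] <- g$genome
    truth[[i]] <- list(ssrs = g$truth$ssrs, n_ssrs_model = counts[i],
                       size = sizes[i])
  }
  list(genomes = genomes, truth = truth,
       model = list(slope = slope, intercept = intercept,
                    noise_sd = noise_sd, sizes = sizes, counts = counts))
}
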