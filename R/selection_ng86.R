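# Nei & Gojobori (1986) pairwise ka/ks with Jukes-Cantor correction.
#
# Sites: each codon position contributes a synonymous fraction equal to the
# proportion of its three possible single-nucleotide changes that preserve
# the encoded amino acid. Changes to stop codons are counted as
# nonsynonymous (the standard NG86 convention), so every position always
# contributes a full site.
#
# Differences: codon pairs differing at k positions are scored over all k!
# single-step substitution pathways; pathways passing through a stop codon
# are excluded from the average. If every pathway for a pair is blocked, the
# unrestricted all-pathway average is used and a note is logged, keeping the
# estimator total-difference-conserving.

NUC <- c("A", "C", "G", "T")

mutate_at <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' @param codon 3-letter string over `A,C,G,T`; must not be a stop codon.
#' @param code genetic code id (see [genetic_code()]).
#' @return numeric vector `c(s, n)` with `s + n = 3`.
#' @export
codon_sites <- function(codon, code = 5) {
  gc <- genetic_code(code)
  codon <- toupper(codon)
  if (is.na(gc[codon]) || nchar(codon) != 3L) stop("invalid codon: ", codon)
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon ", codon, " has no site counts")
  s <- 0
  for (pos in 1:3) {
    from <- substr(codon, pos, pos)
    for (b in setdiff(NUC, from)) {
      if (gc[[mutate_at(codon, pos, b)]] == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# all k! orderings of a position vector (k <= 3)
path_orders <- function(pos) {
  k <- length(pos)
  if (k == 1L) return(list(pos))
  if (k == 2L) return(list(pos, rev(pos)))
  out <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    out[[length(out) + 1L]] <- c(pos[i], pos[j], pos[setdiff(1:3, c(i, j))])
  }
  out
}

# pathway-averaged (sd, nd) for one codon pair; attribute 'blocked' marks the
# unrestricted fallback
codon_pair_diffs <- function(ca, cb, gc) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  score_path <- function(ord, allow_stop) {
    cur <- ca
    sd <- nd <- 0
    for (p in ord) {
      nxt <- mutate_at(cur, p, substr(cb, p, p))
      if (!allow_stop && gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  orders <- path_orders(pos)
  scored <- lapply(orders, score_path, allow_stop = FALSE)
  scored <- scored[!vapply(scored, is.null, logical(1))]
  blocked <- FALSE
  if (!length(scored)) {
    blocked <- TRUE
    scored <- lapply(orders, score_path, allow_stop = TRUE)
  }
  m <- colMeans(do.call(rbind, scored))
  out <- c(sd = m[1], nd = m[2])
  attr(out, "blocked") <- blocked
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori ka/ks for a codon-aligned sequence pair
#'
#' Site counts (S, N) are averaged over the two sequences; difference counts
#' (Sd, Nd) are averaged over all substitution pathways (stop-avoiding, with
#' a logged unrestricted fallback). Proportions are Jukes-Cantor corrected:
#' `d = -3/4 log(1 - 4p/3)`.
#'
#' Codon pairs containing a gap (`-`) or `N` in either sequence are skipped;
#' codon pairs where either codon is a stop are skipped with a warning
#' (stops are expected to be excluded upstream).
#'
#' @param seqA,seqB codon-aligned nucleotide strings of equal length
#'   divisible by 3.
#' @param code genetic code id.
#' @param ids length-2 character vector naming the pair.
#' @return An object of class `kaks_result`: list with `ids`, `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `ks`, `ka`, `omega` (NA when `ks` is 0 or
#'   undefined), `codons_used`, `n_blocked_pathpairs`.
#' @export
pairwise_ng86 <- function(seqA, seqB, code = 5, ids = c("A", "B")) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences must be codon-aligned (equal length)")
  if (nchar(seqA) %% 3L != 0L) stop("aligned length not divisible by 3")
  gc <- genetic_code(code)
  ca <- split_codons(seqA)
  cb <- split_codons(seqB)
  usable <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  is_stop_pair <- logical(length(ca))
  is_stop_pair[usable] <- gc[ca[usable]] == "*" | gc[cb[usable]] == "*"
  if (any(is_stop_pair)) {
    warning("skipping ", sum(is_stop_pair), " codon pair(s) involving stop codons")
  }
  usable <- usable & !is_stop_pair
  if (!any(usable)) stop("zero overlapping codons after filtering")
  S <- N <- Sd <- Nd <- 0
  n_blocked <- 0L
  for (i in which(usable)) {
    sa <- codon_sites_cached(ca[i], gc)
    sb <- codon_sites_cached(cb[i], gc)
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    d <- codon_pair_diffs(ca[i], cb[i], gc)
    if (isTRUE(attr(d, "blocked"))) n_blocked <- n_blocked + 1L
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (n_blocked > 0L) {
    message(n_blocked, " codon pair(s) had all stop-avoiding pathways blocked; ",
            "unrestricted pathway average used")
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)) {
    warning("proportion of differences >= 3/4: Jukes-Cantor distance undefined")
  }
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ids = ids, S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, ks = ks, ka = ka, omega = omega,
                 codons_used = sum(usable),
                 n_blocked_pathpairs = n_blocked),
            class = "kaks_result")
}

# per-codon site counts memoised against the 64-codon table of one code
codon_sites_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(codon, gc) {
    key <- paste0(codon, attr(gc, "id", exact = TRUE), gc[["ATA"]], gc[["TGA"]],
                  gc[["AGA"]])
    if (!is.null(cache[[key]])) return(cache[[key]])
    aa <- gc[[codon]]
    s <- 0
    for (pos in 1:3) {
      from <- substr(codon, pos, pos)
      for (b in setdiff(NUC, from)) {
        if (gc[[mutate_at(codon, pos, b)]] == aa) s <- s + 1 / 3
      }
    }
    cache[[key]] <- c(s, 3 - s)
    cache[[key]]
  }
})

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %s vs %s: %d codons\n", x$ids[1], x$ids[2],
              x$codons_used))
  cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f  ks=%s ka=%s omega=%s\n",
              x$S, x$N, x$Sd, x$Nd,
              format(x$ks, digits = 4), format(x$ka, digits = 4),
              format(x$omega, digits = 4)))
  invisible(x)
}

#' Per-gene omega summary across a set of taxa
#'
#' Runs [pairwise_ng86()] over all unordered taxon pairs of one gene
#' alignment and aggregates. The headline omega is the ratio of means
#' (mean ka / mean ks), which is robust to pairs with ks near 0; the mean of
#' pairwise ratios is reported alongside for comparison.
#'
#' @param alignment named character vector (or list), taxon -> codon-aligned
#'   in-frame sequence; >= 2 taxa.
#' @param code genetic code id.
#' @param gene gene label for the output.
#' @return An object of class `gene_omega`: list with `gene`, `mean_ka`,
#'   `mean_ks`, `omega` (ratio of means), `omega_mean_of_ratios`, `n_pairs`
#'   (pairs with defined ka and ks), `pairs` (per-pair data.frame).
#' @export
gene_omega <- function(alignment, code = 5, gene = "gene") {
  alignment <- unlist(alignment)
  if (length(alignment) < 2L) stop("need >= 2 taxa")
  taxa <- names(alignment)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(alignment))
  idx <- utils::combn(length(alignment), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    r <- pairwise_ng86(alignment[[i1]], alignment[[i2]], code = code,
                       ids = taxa[c(i1, i2)])
    data.frame(taxon1 = taxa[i1], taxon2 = taxa[i2], ka = r$ka, ks = r$ks,
               omega = r$omega, codons = r$codons_used,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  ok <- !is.na(pairs$ka) & !is.na(pairs$ks)
  if (!any(ok)) {
    warning("all pairs undefined for ", gene)
    return(structure(list(gene = gene, mean_ka = NA_real_, mean_ks = NA_real_,
                          omega = NA_real_, omega_mean_of_ratios = NA_real_,
                          n_pairs = 0L, pairs = pairs),
                     class = "gene_omega"))
  }
  mean_ka <- mean(pairs$ka[ok])
  mean_ks <- mean(pairs$ks[ok])
  omega <- if (mean_ks > 0) mean_ka / mean_ks else NA_real_
  mor <- if (any(!is.na(pairs$omega))) mean(pairs$omega, na.rm = TRUE) else NA_real_
  structure(list(gene = gene, mean_ka = mean_ka, mean_ks = mean_ks,
                 omega = omega, omega_mean_of_ratios = mor,
                 n_pairs = sum(ok), pairs = pairs),
            class = "gene_omega")
}

#' @export
print.gene_omega <- function(x, ...) {
  cat(sprintf("<gene_omega> %s: mean ka=%.4f mean ks=%.4f omega=%.4f (%d pairs)\n",
              x$gene, x$mean_ka, x$mean_ks, x$omega, x$n_pairs))
  invisible(x)
}

#' ka/ks summary table over multiple genes
#'
#' @param gene_alignments named list: gene -> named vector of codon-aligned
#'   sequences across taxa.
#' @param code genetic code id.
#' @return data.frame (gene, mean_ka, mean_ks, omega, omega_mean_of_ratios,
#'   n_pairs), sorted by omega ascending (most conserved first), with the
#'   per-gene `gene_omega` objects attached as attribute `details`.
#' @export
kaks_table <- function(gene_alignments, code = 5) {
  res <- lapply(names(gene_alignments), function(g) {
    gene_omega(gene_alignments[[g]], code = code, gene = g)
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(gene = r$gene, mean_ka = r$mean_ka, mean_ks = r$mean_ks,
               omega = r$omega, omega_mean_of_ratios = r$omega_mean_of_ratios,
               n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$omega), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "details") <- setNames(res, vapply(res, `[[`, "", "gene"))
  out
}
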