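# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately use naive all-cases
# enumeration, not the package's algorithms.

rand_seq <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# exhaustive all-substrings perfect-repeat enumerator -------------------------

oracle_primitive <- function(motif) {
  p <- nchar(motif)
  !any(vapply(seq_len(p - 1), function(d) {
    p %% d == 0 && identical(motif, strrep(substr(motif, 1, d), p / d))
  }, logical(1)))
}

oracle_scan <- function(seq, min_units = c(12, 6, 4, 3, 3, 3)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (p in 1:6) {
    for (i in seq_len(max(0, n - p))) {
      ok <- function(j) {
        j >= 1 && j + p <= n && ch[j] != "N" && ch[j + p] != "N" &&
          ch[j] == ch[j + p]
      }
      if (!ok(i)) next
      if (ok(i - 1)) next                      # not left-maximal
      t <- 0
      while (ok(i + t)) t <- t + 1
      units <- (t + p) %/% p
      if (units < min_units[p]) next
      motif <- paste(ch[i:(i + p - 1)], collapse = "")
      if (!oracle_primitive(motif)) next
      rows[[length(rows) + 1]] <- data.frame(
        motif = motif, n_units = units, size = units * p,
        start = i, end = i + units * p - 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), n_units = integer(),
                      size = integer(), start = integer(), end = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

# exhaustive NG86 site and pathway enumerators ---------------------------------

oracle_codon_sites <- function(codon, gc) {
  aa <- gc[[codon]]
  syn <- 0L
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] == aa) syn <- syn + 1L
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# all orderings via recursive enumeration
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pair_diffs <- function(ca, cb, gc) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  walk <- function(order) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") return(list(valid = FALSE, sd = sd, nd = nd,
                                     stopped = TRUE))
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(valid = TRUE, sd = sd, nd = nd)
  }
  paths <- lapply(oracle_perms(pos), walk)
  valid <- Filter(function(x) x$valid, paths)
  use <- if (length(valid)) valid else {
    # unrestricted: rewalk counting through stops
    lapply(oracle_perms(pos), function(order) {
      cur <- a
      sd <- nd <- 0
      for (p in order) {
        nxt <- cur
        nxt[p] <- b[p]
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]) {
          sd <- sd + 1
        } else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd)
    })
  }
  c(sd = mean(vapply(use, function(x) x$sd, numeric(1))),
    nd = mean(vapply(use, function(x) x$nd, numeric(1))))
}

random_codon <- function(gc, no_stop = TRUE) {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    if (!no_stop || gc[[cd]] != "*") return(cd)
  }
}

# embed a repeat-bearing core between flanks verified to neither contain
# repeats nor extend the core's repeats across the junctions
with_clean_flanks <- function(core, n = 40) {
  cc <- scan_ssrs(core)
  repeat {
    s <- paste0(rand_seq(n, probs = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)),
                core,
                rand_seq(n, probs = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)))
    sc <- scan_ssrs(s)
    if (nrow(sc) == nrow(cc) && all(sc$motif == cc$motif) &&
        all(sc$start == cc$start + n) && all(sc$n_units == cc$n_units)) {
      return(s)
    }
  }
}

# per-character composition counter (independent of count_bases)
oracle_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  table(factor(ch, levels = c("A", "C", "G", "T", "N")))
}

# small in-memory GenBank record builder for reader tests
make_genbank <- function(identifier, seq, features, circular = TRUE) {
  loc_str <- function(i) {
    base <- paste0(features$start[i], "..", features$end[i])
    if (features$strand[i] == "-") paste0("complement(", base, ")") else base
  }
  key <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           control_region = "D-loop", pseudogene = "CDS")
  lines <- c(
    sprintf("LOCUS       %s %d bp DNA %s INV 01-JAN-2024", identifier,
            nchar(seq), if (circular) "circular" else "linear"),
    sprintf("ACCESSION   %s", identifier),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)))
  for (i in seq_len(nrow(features))) {
    lines <- c(lines,
      sprintf("     %-15s %s", key[[features$kind[i]]], loc_str(i)),
      sprintf("                     /gene=\"%s\"", features$name[i]))
    if (features$kind[i] == "pseudogene") {
      lines <- c(lines, "                     /pseudo")
    }
  }
  lines <- c(lines, "ORIGIN")
  for (o in seq(1, nchar(seq), by = 60)) {
    lines <- c(lines, sprintf("%9d %s", o,
                              tolower(substr(seq, o, min(nchar(seq), o + 59)))))
  }
  c(lines, "//")
}
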