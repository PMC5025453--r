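# Fixture builders and independent brute-force oracles used across the
# suite.  Oracles deliberately re-derive results by enumeration or
# base-by-base counting, never by calling the code path they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

random_aa <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
random_nt <- function(n) paste(sample(NT4, n, TRUE), collapse = "")

# Random CDS of n_codons sense codons (no stops).
random_cds <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, TRUE), collapse = "")
}

# Single-transcript plus/minus-strand gene model from exon widths and
# intron widths, with the CDS covering spliced [cds_from, cds_to).
make_model <- function(exon_w, intron_w = integer(), cds_from = 0,
                       cds_to = sum(exon_w), strand = "+", gstart = 100,
                       id = "g1") {
  stopifnot(length(intron_w) == length(exon_w) - 1)
  exons <- matrix(0L, length(exon_w), 2)
  at <- gstart
  for (e in seq_along(exon_w)) {
    exons[e, ] <- c(at, at + exon_w[e])
    at <- at + exon_w[e] + if (e < length(exon_w)) intron_w[e] else 0L
  }
  # spliced interval (plus orientation) -> genomic spans
  sp2gen <- function(lo, hi) {
    out <- NULL; acc <- 0L
    for (e in seq_len(nrow(exons))) {
      w <- exons[e, 2] - exons[e, 1]
      s <- max(lo, acc); t <- min(hi, acc + w)
      if (s < t) out <- rbind(out, c(exons[e, 1] + (s - acc),
                                     exons[e, 1] + (t - acc)))
      acc <- acc + w
    }
    out
  }
  cds <- if (cds_to > cds_from) sp2gen(cds_from, cds_to) else NULL
  tx <- list(exons = exons, cds = cds)
  gene_model(id, "chrT", strand, stats::setNames(list(tx), paste0(id, ".1")))
}

# Oracle: intron phases by walking the transcript base-by-base.
phases_oracle <- function(model, tx_id) {
  tx <- model$transcripts[[tx_id]]
  ex <- tx$exons
  ord <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  in_cds <- function(g) any(g >= tx$cds[, 1] & g < tx$cds[, 2])
  cds_total <- sum(tx$cds[, 2] - tx$cds[, 1])
  phases <- integer(0)
  cds_seen <- 0L
  for (k in seq_along(ord)) {
    e <- ord[k]
    gpos <- if (model$strand == "+") ex[e, 1]:(ex[e, 2] - 1L)
            else (ex[e, 2] - 1L):ex[e, 1]
    for (g in gpos) if (in_cds(g)) cds_seen <- cds_seen + 1L
    if (k < length(ord)) {
      ph <- cds_seen %% 3L
      if (cds_seen == 0L || cds_seen == cds_total) ph <- NA_integer_
      phases <- c(phases, ph)
    }
  }
  phases
}

# Oracle: all signature matches by full expansion of the degenerate
# pattern followed by fixed-string search.
expand_pattern <- function(pattern) {
  sets <- mapkcascades:::parse_signature(pattern)
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

signature_oracle <- function(sequence, signatures = kinase_signatures()) {
  hits <- list()
  for (fam in names(signatures)) {
    for (exp_ in expand_pattern(signatures[[fam]])) {
      start <- 1
      repeat {
        p <- regexpr(exp_, substring(sequence, start), fixed = TRUE)
        if (p == -1) break
        hits[[length(hits) + 1L]] <- data.frame(
          subfamily = fam, position = start + p - 2L,  # 0-based
          match = exp_, stringsAsFactors = FALSE)
        start <- start + p
      }
    }
  }
  out <- do.call(rbind, c(hits, list(data.frame(
    subfamily = character(), position = integer(), match = character(),
    stringsAsFactors = FALSE))))
  out <- unique(out)
  out <- out[order(out$position, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Oracle: IUPAC scan by per-position set membership on both strands.
iupac_sets <- mapkcascades:::IUPAC_SETS
iupac_match_at <- function(seqchars, motifchars, start) {  # start 0-based
  k <- length(motifchars)
  if (start + k > length(seqchars)) return(FALSE)
  for (p in seq_len(k)) {
    set <- iupac_sets[[motifchars[p]]]
    ch <- seqchars[start + p]
    if (ch == "N") { if (length(set) != 4) return(FALSE) }
    else if (!(ch %in% set)) return(FALSE)
  }
  TRUE
}

scan_oracle <- function(sequence, motifs) {
  seqchars <- strsplit(sequence, "")[[1]]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
  rcchars <- strsplit(rc, "")[[1]]
  L <- length(seqchars)
  hits <- list()
  for (nm in names(motifs)) {
    mc <- strsplit(motifs[[nm]], "")[[1]]
    k <- length(mc)
    for (s in 0:(L - k)) {
      if (iupac_match_at(seqchars, mc, s))
        hits[[length(hits) + 1L]] <- data.frame(
          motif = nm, start = s, strand = "+", stringsAsFactors = FALSE)
      if (iupac_match_at(rcchars, mc, s))
        hits[[length(hits) + 1L]] <- data.frame(
          motif = nm, start = L - s - k, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(hits, list(data.frame(
    motif = character(), start = integer(), strand = character(),
    stringsAsFactors = FALSE))))
  out[order(out$start, out$strand, out$motif), , drop = FALSE]
}

# Oracle: best global affine-gap alignment score by exhaustive
# enumeration of move strings (diagonal / up / left) for tiny inputs.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = -2, gap_ext = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i > length(ca) && j > length(cb)) {
      # score the complete move string, charging gap_open at run starts
      score <- 0; ai <- 1; bi <- 1; prev <- ""
      for (m in moves) {
        if (m == "D") {
          score <- score + if (ca[ai] == cb[bi]) match else mismatch
          ai <- ai + 1; bi <- bi + 1
        } else {
          score <- score + if (m == prev) gap_ext else gap_open
          if (m == "U") ai <- ai + 1 else bi <- bi + 1
        }
        prev <- m
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) recurse(i + 1, j + 1, c(moves, "D"))
    if (i <= length(ca)) recurse(i + 1, j, c(moves, "U"))
    if (j <= length(cb)) recurse(i, j + 1, c(moves, "L"))
  }
  recurse(1, 1, character())
  best
}

# Oracle: Mutual Rank by pairwise counting (no sorting).
mr_oracle <- function(pcc) {
  ids <- rownames(pcc)
  n <- nrow(pcc)
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    1 + sum(vapply(setdiff(others, j), function(k)
      pcc[i, k] > pcc[i, j] ||
        (pcc[i, k] == pcc[i, j] && ids[k] < ids[j]), TRUE))
  }
  mr <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    mr[i, j] <- sqrt(rank_of(i, j) * rank_of(j, i))
  mr
}

# Oracle: cascade triads by triple loop over all gene triples.
triads_oracle <- function(edges, families, localizations) {
  genes <- names(families)
  has_edge <- function(x, y) any((edges$gene_a == x & edges$gene_b == y) |
                                 (edges$gene_a == y & edges$gene_b == x))
  out <- list()
  for (a in genes[families == "MAPKKK"])
    for (k in genes[families == "MKK"])
      for (p in genes[families == "MPK"])
        if (has_edge(a, k) && has_edge(k, p) &&
            localizations[[a]] == localizations[[k]] &&
            localizations[[k]] == localizations[[p]])
          out[[length(out) + 1L]] <- c(a, k, p)
  out
}

# Oracle: closed-form balanced two-way ANOVA with interaction.
anova_oracle <- function(y, fa, fb) {
  fa <- as.factor(fa); fb <- as.factor(fb)
  r <- table(fa, fb)[1]
  a <- nlevels(fa); b <- nlevels(fb)
  gm <- mean(y)
  ma <- tapply(y, fa, mean); mb <- tapply(y, fb, mean)
  mab <- tapply(y, interaction(fa, fb), mean)
  cell <- outer(levels(fa), levels(fb),
                function(x, z) mab[paste(x, z, sep = ".")])
  ss_a <- r * b * sum((ma - gm)^2)
  ss_b <- r * a * sum((mb - gm)^2)
  ss_cells <- r * sum((cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - mab[paste(fa, fb, sep = ".")])^2)
  df_e <- a * b * (r - 1)
  list(F_a = (ss_a / (a - 1)) / (ss_e / df_e),
       F_b = (ss_b / (b - 1)) / (ss_e / df_e),
       F_ab = (ss_ab / ((a - 1) * (b - 1))) / (ss_e / df_e))
}

# Least-squares fit of a 4-taxon unrooted topology to a distance matrix;
# returns the residual sum of squares.  Topologies given as the pair
# grouped together, e.g. c("A","B") for the AB|CD split.
ls_fit_quartet <- function(d, pair) {
  taxa <- rownames(d)
  others <- setdiff(taxa, pair)
  # branch order: tip1, tip2, tip3, tip4, internal
  tips <- c(pair, others)
  combos <- t(combn(4, 2))
  X <- matrix(0, nrow(combos), 5)
  y <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    i <- combos[r, 1]; j <- combos[r, 2]
    X[r, i] <- 1; X[r, j] <- 1
    crosses <- (i <= 2) != (j <= 2)
    if (crosses) X[r, 5] <- 1
    y[r] <- d[tips[i], tips[j]]
  }
  fit <- qr.solve(X, y)
  sum((X %*% fit - y)^2)
}

# internal helpers reused by tests
translate_cds_pub <- mapkcascades:::translate_cds
with_seed_pub <- mapkcascades:::with_seed
revcomp_pub <- mapkcascades:::revcomp

# Vectorized position-wise oracle over many same-length sequences held
# as a character matrix; returns (sequence index, 0-based start) pairs.
scan_oracle_hits <- function(seqmat, motif) {
  L <- ncol(seqmat); k <- nchar(motif)
  mc <- strsplit(motif, "")[[1]]
  hits <- NULL
  for (s in 0:(L - k)) {
    ok <- rep(TRUE, nrow(seqmat))
    for (p in seq_len(k)) {
      set <- iupac_sets[[mc[p]]]
      col <- seqmat[, s + p]
      m <- col %in% set
      if (length(set) == 4) m <- m | col == "N"
      ok <- ok & m
      if (!any(ok)) break
    }
    if (any(ok)) hits <- rbind(hits, cbind(which(ok), s))
  }
  hits
}
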