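#' Alignment scoring parameters
#'
#' @param match,mismatch scores used when `matrix` is `NULL`.
#' @param matrix optional named substitution matrix (e.g. BLOSUM62).
#' @param gap_open score of the first position of a gap (negative).
#' @param gap_extend score of each further gap position (negative).
#' @return list of class `"align_params"`.
#' @export
align_params <- function(match = 1, mismatch = -1, matrix = NULL,
                         gap_open = -2, gap_extend = -1) {
  structure(list(match = match, mismatch = mismatch, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

default_protein_params <- function() {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  align_params(matrix = b62, gap_open = -10, gap_extend = -1)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gap penalties (Gotoh
#' three-state dynamic program, compiled).  A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.  Tie-breaking is deterministic:
#' diagonal moves are preferred over gaps in the second sequence over
#' gaps in the first.
#'
#' @param seq_a,seq_b sequences (single strings).
#' @param params an [align_params()]; when `NULL`, nucleotide sequences
#'   get match/mismatch +1/-1 with gaps -2/-1, protein sequences BLOSUM62
#'   with gaps -10/-1.
#' @return list of class `"pairwise_alignment"` with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length) and `score`.
#' @export
global_align <- function(seq_a, seq_b, params = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  ca <- strsplit(seq_a, "")[[1]]; cb <- strsplit(seq_b, "")[[1]]
  letters_all <- unique(c(ca, cb))
  if (is.null(params)) {
    params <- if (all(letters_all %in% c("A", "C", "G", "T", "N")))
      align_params() else default_protein_params()
  }
  if (is.null(params$matrix)) {
    alpha <- sort(letters_all)
    sub <- matrix(params$mismatch, length(alpha), length(alpha),
                  dimnames = list(alpha, alpha))
    diag(sub) <- params$match
  } else {
    sub <- params$matrix
    bad <- setdiff(letters_all, rownames(sub))
    if (length(bad))
      stop("letter(s) absent from substitution matrix: ",
           paste(bad, collapse = ", "))
    alpha <- rownames(sub)
  }
  res <- .gotoh_align(match(ca, alpha) - 1L, match(cb, alpha) - 1L,
                      sub, params$gap_open, params$gap_extend)
  decode <- function(idx) {
    ch <- rep("-", length(idx))
    ch[idx >= 0] <- alpha[idx[idx >= 0] + 1L]
    paste(ch, collapse = "")
  }
  structure(list(aligned_a = decode(res$a), aligned_b = decode(res$b),
                 score = res$score, params = params),
            class = "pairwise_alignment")
}

#' Percent identity and coverage of a pairwise alignment
#'
#' Identity is the fraction of matching columns among all columns that
#' are not double gaps, in percent.  Coverage is the number of columns
#' where both sequences have a residue, divided by the length of the
#' longer input sequence.
#'
#' @param alignment a [global_align()] result (or a list with
#'   `aligned_a`/`aligned_b`).
#' @param len_a,len_b original (ungapped) sequence lengths; inferred from
#'   the alignment when omitted.
#' @return list with `identity_pct` and `coverage_frac`.
#' @export
pair_identity_coverage <- function(alignment, len_a = NULL, len_b = NULL) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  len_a <- len_a %||% sum(a != "-")
  len_b <- len_b %||% sum(b != "-")
  both <- a != "-" & b != "-"
  list(identity_pct = 100 * sum(a == b & both) / length(a),
       coverage_frac = sum(both) / max(len_a, len_b))
}

#' Classify tandem duplicate pairs
#'
#' A candidate pair is a tandem duplicate (TD) when both genes lie on the
#' same chromosome separated by at most `max_intervening` other genes (of
#' the supplied gene list), the alignment covers more than
#' `coverage_frac` of the longer gene, and its identity exceeds
#' `identity_pct`.  Qualifying pairs sharing genes are grouped into
#' clusters; one duplication event is counted per cluster while every
#' qualifying pair is listed.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`,
#'   `identity_pct`, `coverage_frac`.
#' @param coords data.frame with columns `gene`, `chrom`, `start`
#'   (any monotone per-chromosome position).
#' @param identity_pct,coverage_frac thresholds (defaults 70 / 0.7).
#' @param max_intervening maximum intervening genes for "tightly linked".
#' @return list with `pairs` (qualifying pairs plus `cluster` id) and
#'   `n_events` (number of clusters).
#' @export
classify_tandem <- function(pairs, coords, identity_pct = 70,
                            coverage_frac = 0.7, max_intervening = 1) {
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), coords$gene)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  coords <- coords[order(coords$chrom, coords$start), ]
  coords$rank <- stats::ave(seq_len(nrow(coords)), coords$chrom,
                            FUN = seq_along)
  idx <- function(g, col) coords[[col]][match(g, coords$gene)]
  same_chr <- idx(pairs$gene_a, "chrom") == idx(pairs$gene_b, "chrom")
  gap <- abs(idx(pairs$gene_a, "rank") - idx(pairs$gene_b, "rank")) - 1L
  ok <- same_chr & gap <= max_intervening &
    pairs$identity_pct > identity_pct &
    pairs$coverage_frac > coverage_frac
  td <- pairs[ok, , drop = FALSE]
  # union-find over genes of qualifying pairs
  parent <- stats::setNames(unique(c(td$gene_a, td$gene_b)),
                            unique(c(td$gene_a, td$gene_b)))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(td)))
    parent[[find(td$gene_a[i])]] <- find(td$gene_b[i])
  roots <- vapply(td$gene_a, find, "")
  td$cluster <- if (nrow(td)) as.integer(factor(roots,
                                                levels = unique(roots)))
                else integer()
  rownames(td) <- NULL
  list(pairs = td, n_events = length(unique(td$cluster)))
}

# Translate a CDS, dropping a terminal stop codon if present.
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Protein-guided codon alignment
#'
#' Threads two coding sequences through a protein alignment: every
#' aligned residue becomes its source codon and every protein gap a
#' `---` triplet, so the codon alignment preserves frame and mirrors the
#' protein alignment column-for-column.
#'
#' @param alignment protein [global_align()] result for the two
#'   translated sequences.
#' @param cds_a,cds_b the coding sequences (terminal stop codons allowed).
#' @return list with gapped `codon_a`, `codon_b`.
#' @export
codon_align <- function(alignment, cds_a, cds_b) {
  thread <- function(aligned, cds, which) {
    prot <- translate_cds(cds)
    degap <- gsub("-", "", aligned)
    if (degap != prot) {
      pos <- which(strsplit(degap, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop(sprintf(
        "translation of cds_%s disagrees with the aligned protein at residue %s",
        which, pos %||% "length"))
    }
    cols <- strsplit(aligned, "")[[1]]
    codons <- substring(cds, seq(1, 3 * nchar(prot), 3),
                        seq(3, 3 * nchar(prot), 3))
    out <- character(length(cols))
    k <- 1L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { out[i] <- codons[k]; k <- k + 1L }
    }
    paste(out, collapse = "")
  }
  list(codon_a = thread(alignment$aligned_a, cds_a, "a"),
       codon_b = thread(alignment$aligned_b, cds_b, "b"))
}

GENCODE <- Biostrings::GENETIC_CODE
NUC <- c("A", "C", "G", "T")

# Fraction of synonymous changes at each position of a codon (stop-codon
# targets count as nonsynonymous).  Returns numeric length 3.
codon_syn_fractions <- function(codon) {
  aa <- GENCODE[[codon]]
  chars <- strsplit(codon, "")[[1]]
  vapply(1:3, function(p) {
    alt <- NUC[NUC != chars[p]]
    neigh <- vapply(alt, function(nt) {
      x <- chars; x[p] <- nt; paste(x, collapse = "")
    }, "")
    sum(GENCODE[neigh] == aa) / 3
  }, 0)
}

.syn_site_cache <- new.env(parent = emptyenv())
syn_sites <- function(codon) {
  v <- .syn_site_cache[[codon]]
  if (is.null(v)) {
    v <- sum(codon_syn_fractions(codon))
    .syn_site_cache[[codon]] <- v
  }
  v
}

# Synonymous / nonsynonymous difference counts between two codons,
# averaged over all mutational pathways; pathways passing through a stop
# codon are excluded unless every pathway does.
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    p <- list()
    for (ord in asplit(perms_of(length(pos)), 1)) p <- c(p, list(pos[ord]))
    p
  }
  tally <- function(order_) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sdnd <- c(0, 0)
    for (p in order_) {
      nxt <- cur; nxt[p] <- tgt[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (GENCODE[[to]] == "*" || GENCODE[[from]] == "*")
        return(NULL)  # pathway through a stop codon
      if (GENCODE[[from]] == GENCODE[[to]]) sdnd[1] <- sdnd[1] + 1
      else sdnd[2] <- sdnd[2] + 1
      cur <- nxt
    }
    sdnd
  }
  res <- lapply(perms, tally)
  ok <- res[!vapply(res, is.null, TRUE)]
  if (length(ok) == 0) {  # all pathways hit stops: count them anyway
    ok <- lapply(perms, function(order_) {
      cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
      sdnd <- c(0, 0)
      for (p in order_) {
        nxt <- cur; nxt[p] <- tgt[p]
        same <- GENCODE[[paste(cur, collapse = "")]] ==
          GENCODE[[paste(nxt, collapse = "")]]
        sdnd <- sdnd + if (same) c(1, 0) else c(0, 1)
        cur <- nxt
      }
      sdnd
    })
  }
  m <- colMeans(do.call(rbind, ok))
  c(sd = m[1], nd = m[2])
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences), accumulates pathway-averaged difference counts for
#' multi-hit codons, and applies the Jukes-Cantor correction
#' `d = -3/4 * ln(1 - 4p/3)`.  Columns containing gaps are skipped;
#' proportions at or beyond the correction's domain (p >= 3/4), and a
#' Ka/Ks ratio with Ks = 0, are returned as `NA` markers.
#'
#' @param codon_a,codon_b gapped, frame-preserving codon sequences of
#'   equal length (from [codon_align()]); internal stop codons are an
#'   error, a terminal stop codon is skipped.
#' @return list with `ka`, `ks`, `ratio` and the underlying counts
#'   `S`, `N`, `Sd`, `Nd`.
#' @export
ng86_kaks <- function(codon_a, codon_b) {
  if (nchar(codon_a) != nchar(codon_b))
    stop("codon alignments differ in length")
  if (nchar(codon_a) %% 3 != 0) stop("alignment length not divisible by 3")
  n_cod <- nchar(codon_a) / 3
  starts <- seq(1, by = 3, length.out = n_cod)
  ca <- substring(codon_a, starts, starts + 2)
  cb <- substring(codon_b, starts, starts + 2)
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(n_cod)) {
    if (grepl("-", ca[i]) || grepl("-", cb[i])) next
    if (GENCODE[[ca[i]]] == "*" || GENCODE[[cb[i]]] == "*") {
      if (i == n_cod) next  # terminal stop codon is allowed, not counted
      stop("internal stop codon at codon ", i)
    }
    used <- used + 1
    S <- S + (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    d <- codon_path_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  N <- 3 * used - S
  jc <- function(p) {
    if (is.nan(p) || p >= 0.75) return(NA_real_)
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(Sd / S)
  ka <- jc(Nd / N)
  list(ka = ka, ks = ks, ratio = kaks_ratio(ka, ks),
       S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Ka/Ks ratio
#'
#' @param ka,ks nonsynonymous and synonymous substitutions per site.
#' @return `ka / ks`, or `NA` when Ks is zero or undefined.
#' @examples
#' kaks_ratio(0.0091, 0.1896)  # 0.047996...
#' @export
kaks_ratio <- function(ka, ks) {
  ifelse(is.na(ka) | is.na(ks) | ks <= 0, NA_real_, ka / ks)
}

#' Date a duplication event from synonymous divergence
#'
#' Under a constant synonymous molecular clock, a pair separated by Ks
#' synonymous substitutions per site diverged `T = Ks / (2 * lambda)`
#' years ago; the result is reported in million years (Myr).
#'
#' @param ks synonymous substitutions per synonymous site.
#' @param lambda_rate clock rate in substitutions/site/year (default
#'   6.1e-9, the grass synonymous rate consistent with the shipped
#'   duplicate-pair table).
#' @return divergence time in Myr.
#' @examples
#' divergence_time(0.1896)  # 15.54 Myr
#' @export
divergence_time <- function(ks, lambda_rate = 6.1e-9) {
  stopifnot(all(ks >= 0), lambda_rate > 0)
  ks / (2 * lambda_rate) / 1e6
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking: when
#' several pairs minimise the Q criterion, the pair whose (sorted)
#' representative labels are lexicographically smallest is joined.  On an
#' additive distance matrix the output tree's patristic distances
#' reproduce the input exactly.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal.
#' @param labels tip labels; defaults to `rownames(d)`.
#' @return Newick string (unrooted; trifurcating root for n >= 3) with
#'   branch lengths.
#' @export
nj_tree <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("asymmetric distance matrix")
  if (any(d < 0)) stop("negative distances")
  if (any(diag(d) != 0)) stop("nonzero diagonal")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", x)
  newick <- labels          # current subtree strings
  rep_lab <- labels         # smallest original label per cluster
  if (n == 2)
    return(paste0("(", newick[1], ":", fmt(d[1, 2] / 2), ",",
                  newick[2], ":", fmt(d[1, 2] / 2), ");"))
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(rep_lab[i], rep_lab[j]))
      if (q[i, j] < best_q - 1e-12 ||
          (abs(q[i, j] - best_q) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, key = key); best_q <- q[i, j]
      }
    }
    i <- best$i; j <- best$j
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (d[i, others] + d[j, others] - d[i, j]) / 2
    node <- paste0("(", newick[i], ":", fmt(bi), ",",
                   newick[j], ":", fmt(bj), ")")
    d <- rbind(cbind(d[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    newick <- c(newick[others], node)
    rep_lab <- c(rep_lab[others], min(best$key))
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  paste0("(", newick[1], ":", fmt(b1), ",", newick[2], ":", fmt(b2), ",",
         newick[3], ":", fmt(b3), ");")
}
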