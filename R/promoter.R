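IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Default cis-regulatory element dictionary
#'
#' IUPAC consensi for the stress- and light-responsive promoter elements
#' the pipeline screens by default: the heat-shock element (HSE) and
#' TCA-element (heat / salicylic acid), ABRE and motif-IIb (abscisic
#' acid), CGTCA- and TGACG-motifs (MeJA) and the circadian element.
#' Elements without a published consensus (sp1, G-box, ACE, 3-AF1) must
#' be supplied by the user.
#'
#' @return named character vector of IUPAC consensi.
#' @export
default_motifs <- function() {
  c(HSE = "AAAAAATTTC",
    `TCA-element` = "GAGAAGAATA",
    ABRE = "CCGCGTAGGC",
    `motif-IIb` = "CCGCCGCGC",
    `CGTCA-motif` = "CGTCA",
    `TGACG-motif` = "TGACG",
    circadian = "CAANNNNATC")
}

validate_motifs <- function(motifs) {
  stopifnot(!is.null(names(motifs)), !anyDuplicated(names(motifs)))
  for (nm in names(motifs)) {
    bad <- setdiff(strsplit(toupper(motifs[[nm]]), "")[[1]],
                   names(IUPAC_SETS))
    if (length(bad))
      stop("invalid IUPAC code(s) in motif '", nm, "': ",
           paste(unique(bad), collapse = ", "))
  }
  invisible(toupper(motifs))
}

# Regex character class for one IUPAC motif position.  A sequence 'N'
# matches only positions whose allowed set is all four bases, so
# ambiguous sequence cannot create specific-element hits.
iupac_regex <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 4) "[ACGTN]"
    else if (length(set) == 1) set
    else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

revcomp <- function(seqs)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))

scan_one_strand <- function(sequence, motifs) {
  hits <- list()
  for (nm in names(motifs)) {
    rx <- paste0("(?=(", iupac_regex(motifs[[nm]]), "))")
    m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    if (m[1] != -1) {
      k <- nchar(motifs[[nm]])
      starts <- as.integer(m) - 1L
      hits[[nm]] <- data.frame(
        motif = nm, start = starts,
        match = substring(sequence, starts + 1L, starts + k),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(hits, list(data.frame(motif = character(),
                                         start = integer(),
                                         match = character(),
                                         stringsAsFactors = FALSE))))
}

#' Scan sequences for IUPAC consensus elements on both strands
#'
#' Reports every (possibly overlapping) occurrence of each dictionary
#' element on the plus and minus strand of each sequence.  Minus-strand
#' hits are reported at their plus-strand start coordinate and carry the
#' matched plus-strand substring.  Sequence `N`s match only motif
#' positions whose allowed set is all four bases.
#'
#' @param sequences named character vector of nucleotide sequences (a
#'   single unnamed sequence is also accepted).
#' @param motifs named IUPAC dictionary, see [default_motifs()].
#' @return data.frame with `seq_id`, `motif`, `start` (0-based), `strand`,
#'   `match`, sorted by (seq_id, start, strand, motif).
#' @examples
#' scan_motifs(c(p1 = "TTCAAGGGGATCTT"))
#' @export
scan_motifs <- function(sequences, motifs = default_motifs()) {
  motifs <- validate_motifs(motifs)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- toupper(sequences)
  rc_all <- revcomp(sequences)  # one vectorized pass for all sequences
  out <- list()
  for (id in names(sequences)) {
    seqv <- sequences[[id]]
    L <- nchar(seqv)
    plus <- scan_one_strand(seqv, motifs)
    if (nrow(plus)) plus$strand <- "+"
    minus <- scan_one_strand(rc_all[[id]], motifs)
    if (nrow(minus)) {
      minus$strand <- "-"
      k <- nchar(motifs[minus$motif])
      minus$start <- L - minus$start - k           # plus-strand coordinate
      minus$match <- substring(seqv, minus$start + 1L, minus$start + k)
    }
    h <- rbind(plus, minus)
    if (nrow(h)) {
      h$seq_id <- id
      h <- h[order(h$start, h$strand, h$motif),
             c("seq_id", "motif", "start", "strand", "match")]
      out[[id]] <- h
    }
  }
  res <- do.call(rbind, c(out, list(data.frame(
    seq_id = character(), motif = character(), start = integer(),
    strand = character(), match = character(), stringsAsFactors = FALSE))))
  rownames(res) <- NULL
  res
}

#' Element count and presence profile per gene
#'
#' @param hits data.frame from [scan_motifs()].
#' @param genes gene / sequence ids defining the rows of the profile.
#' @param motifs motif dictionary defining the columns.
#' @return list with `counts` (genes x elements integer matrix) and
#'   `presence` (logical matrix, count >= 1).
#' @export
element_profile <- function(hits, genes, motifs = default_motifs()) {
  counts <- matrix(0L, length(genes), length(motifs),
                   dimnames = list(genes, names(motifs)))
  for (i in seq_len(nrow(hits))) {
    if (hits$seq_id[i] %in% genes)
      counts[hits$seq_id[i], hits$motif[i]] <-
        counts[hits$seq_id[i], hits$motif[i]] + 1L
  }
  list(counts = counts, presence = counts >= 1L)
}

#' Extract promoter windows upstream of gene models
#'
#' Takes the `len` bases immediately upstream of each gene's
#' transcription start (strand-aware; the window is reported 5'->3' on
#' the gene's strand), truncating at the contig edge.
#'
#' @param models list of [gene_model()] objects.
#' @param genome named character vector of contig sequences.
#' @param len window length in bases (default 2000).
#' @return named character vector of promoter sequences.
#' @export
extract_promoters <- function(models, genome, len = 2000) {
  out <- character(0)
  for (gm in models) {
    contig <- genome[[gm$chrom]]
    if (is.null(contig)) stop("contig '", gm$chrom, "' absent from genome")
    span <- range(unlist(lapply(gm$transcripts, function(t) t$exons)))
    if (gm$strand == "+") {
      from <- max(0L, span[1] - len)
      s <- substr(contig, from + 1L, span[1])
    } else {
      to <- min(nchar(contig), span[2] + len)
      s <- revcomp(substr(contig, span[2] + 1L, to))
    }
    out[gm$gene_id] <- s
  }
  out
}
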