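# Span helpers (0-based half-open genomic coordinates).
span_widths <- function(m) if (nrow(m) == 0) integer() else m[, 2] - m[, 1]

# Total overlap of spans `m` with the genomic interval [lo, hi).
span_overlap <- function(m, lo, hi) {
  if (nrow(m) == 0) return(0L)
  sum(pmax(0L, pmin(m[, 2], hi) - pmax(m[, 1], lo)))
}

get_transcript <- function(model, tx_id) {
  tx <- model$transcripts[[tx_id]]
  if (is.null(tx))
    stop("unknown transcript '", tx_id, "' in gene ", model$gene_id)
  tx
}

# Introns of a transcript in genomic order: gaps between consecutive exons.
transcript_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2) return(matrix(integer(), ncol = 2,
                           dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, 2], end = ex[-1, 1])
}

# CDS bases 5' (in transcript orientation) of each intron boundary.
cds_upstream_of_introns <- function(tx, strand) {
  intr <- transcript_introns(tx)
  if (nrow(intr) == 0) return(integer())
  up <- vapply(seq_len(nrow(intr)), function(j) {
    if (strand == "+") span_overlap(tx$cds, -1L, intr[j, 1])
    else span_overlap(tx$cds, intr[j, 2], .Machine$integer.max)
  }, 0)
  if (strand == "-") up <- rev(up)  # transcript orientation
  as.integer(up)
}

#' Transcript-level nucleotide features
#'
#' Computes cDNA, 5'UTR, CDS and 3'UTR lengths (in transcript
#' orientation) and the intron count for one transcript of a gene model.
#' The sum identity `cdna = utr5 + cds + utr3` always holds: UTR lengths
#' are derived as the exonic bases 5' and 3' of the CDS.
#'
#' @param model a [gene_model()].
#' @param tx_id transcript id.
#' @return list with `cdna_len`, `utr5_len`, `cds_len`, `utr3_len`,
#'   `intron_count`.
#' @export
transcript_features <- function(model, tx_id) {
  tx <- get_transcript(model, tx_id)
  cdna <- sum(span_widths(tx$exons))
  cds <- sum(span_widths(tx$cds))
  if (cds > 0) {
    # exonic bases 5' of the CDS start, in transcript orientation
    if (model$strand == "+")
      utr5 <- span_overlap(tx$exons, -1L, min(tx$cds[, 1]))
    else
      utr5 <- span_overlap(tx$exons, max(tx$cds[, 2]), .Machine$integer.max)
  } else utr5 <- 0L
  utr3 <- cdna - utr5 - cds
  list(cdna_len = as.integer(cdna), utr5_len = as.integer(utr5),
       cds_len = as.integer(cds), utr3_len = as.integer(utr3),
       intron_count = nrow(tx$exons) - 1L)
}

#' Splice-site phases of a transcript's introns
#'
#' The phase of an intron is the number of CDS bases upstream of it
#' (in transcript orientation) modulo 3: phase 0 introns fall between
#' codons, phases 1 and 2 interrupt a codon after one or two bases.
#' Introns lying outside the CDS (entirely within a UTR) are reported
#' with phase `NA`, the distinct "undefined" marker.
#'
#' @inheritParams transcript_features
#' @return integer vector of phases (0/1/2 or NA) in transcript
#'   orientation, one per intron.
#' @export
intron_phases <- function(model, tx_id) {
  tx <- get_transcript(model, tx_id)
  cds_len <- sum(span_widths(tx$cds))
  if (cds_len == 0 || cds_len %% 3 != 0)
    stop("incomplete CDS (length ", cds_len, ") in transcript ", tx_id)
  up <- cds_upstream_of_introns(tx, model$strand)
  phases <- up %% 3L
  phases[up == 0L | up == cds_len] <- NA_integer_  # UTR introns
  phases
}

#' Intron pattern within the kinase-domain codon range
#'
#' Restricts the intron/phase profile to the introns that interrupt the
#' codons encoding the kinase domain; within a subfamily this pattern is
#' strongly conserved and supports phylogenetic groupings.
#'
#' @inheritParams transcript_features
#' @param domain_span protein-coordinate span of the kinase domain,
#'   0-based half-open `c(start, end)`.
#' @return list with `count` and `phases` (restricted to domain introns).
#' @export
domain_intron_pattern <- function(model, tx_id, domain_span) {
  tx <- get_transcript(model, tx_id)
  cds_len <- sum(span_widths(tx$cds))
  dom <- as.integer(domain_span) * 3L
  if (dom[1] < 0 || dom[2] > cds_len)
    stop("kinase-domain span outside the CDS")
  up <- cds_upstream_of_introns(tx, model$strand)
  inside <- up > dom[1] & up < dom[2]
  list(count = sum(inside), phases = (up %% 3L)[inside])
}

#' Structural difference between two transcripts of one gene
#'
#' Classifies how two splice isoforms differ: number of extra introns,
#' whether the differing introns sit toward the 5' or 3' end of the
#' transcript, whether any fall inside the kinase-domain codon range, and
#' whether the terminal exon is extended.
#'
#' @inheritParams transcript_features
#' @param tx1,tx2 the two transcript ids (`tx2` compared against `tx1`).
#' @param domain_span optional protein-coordinate kinase-domain span used
#'   to call `region` (`"inside"`/`"outside"` the domain).
#' @return list with `identical`, `extra_introns`, `end`
#'   (`"5'"`, `"3'"` or `"none"`), `region`, `extension`.
#' @export
isoform_structure_diff <- function(model, tx1, tx2, domain_span = NULL) {
  t1 <- get_transcript(model, tx1)
  t2 <- get_transcript(model, tx2)
  key <- function(m) if (nrow(m) == 0) character() else
    paste(m[, 1], m[, 2], sep = "-")
  if (identical(key(t1$exons), key(t2$exons)))
    return(list(identical = TRUE, extra_introns = 0L, end = "none",
                region = "none", extension = FALSE))
  i1 <- transcript_introns(t1); i2 <- transcript_introns(t2)
  diff_keys <- c(setdiff(key(i2), key(i1)), setdiff(key(i1), key(i2)))
  extra <- nrow(i2) - nrow(i1)

  # transcript-orientation position of each differing intron, as a
  # fraction of the cDNA of the transcript it belongs to
  frac_of <- function(tx, ikeys) {
    intr <- transcript_introns(tx)
    sel <- key(intr) %in% ikeys
    if (!any(sel)) return(numeric())
    cdna <- sum(span_widths(tx$exons))
    pos <- vapply(which(sel), function(j) {
      if (model$strand == "+") span_overlap(tx$exons, -1L, intr[j, 1])
      else span_overlap(tx$exons, intr[j, 2], .Machine$integer.max)
    }, 0)
    pos / cdna
  }
  fracs <- c(frac_of(t2, diff_keys), frac_of(t1, diff_keys))
  end <- if (length(fracs) == 0) "none"
         else if (mean(fracs) >= 0.5) "3'" else "5'"

  region <- "outside"
  if (!is.null(domain_span)) {
    dom <- as.integer(domain_span) * 3L
    in_dom <- function(tx, ikeys) {
      intr <- transcript_introns(tx)
      sel <- key(intr) %in% ikeys
      if (!any(sel)) return(FALSE)
      up <- cds_upstream_of_introns(tx, model$strand)
      ord <- if (model$strand == "-") rev(seq_len(nrow(intr))) else
        seq_len(nrow(intr))
      any(up[match(which(sel), ord)] > dom[1] &
          up[match(which(sel), ord)] < dom[2])
    }
    if (in_dom(t2, diff_keys) || in_dom(t1, diff_keys)) region <- "inside"
  }

  # terminal (3'-most in transcript orientation) exon boundary change
  term1 <- if (model$strand == "+") max(t1$exons[, 2]) else min(t1$exons[, 1])
  term2 <- if (model$strand == "+") max(t2$exons[, 2]) else min(t2$exons[, 1])
  list(identical = FALSE, extra_introns = as.integer(extra), end = end,
       region = region, extension = term1 != term2)
}
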