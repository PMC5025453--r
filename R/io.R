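#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] enforcing the
#' pipeline's contract: record ids must be unique, records must be
#' non-empty, and sequences are upper-cased.  Ids are taken as the first
#' whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0))
    stop("empty FASTA record(s): ",
         paste(ids[Biostrings::width(set) == 0], collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model holds one gene's transcript structures in genomic
#' coordinates.  All spans are 0-based half-open; the on-disk GFF3
#' convention (1-based closed) is converted at the I/O boundary only.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts named list; each element a list with integer
#'   two-column matrices `exons`, `cds`, and optionally `utr5`, `utr3`
#'   (columns: start, end; 0-based half-open, genomic coordinates).
#' @return an object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1,
            !is.null(names(transcripts)))
  transcripts <- lapply(transcripts, function(tx) {
    tx$exons <- sort_spans(tx$exons)
    tx$cds <- sort_spans(tx$cds)
    for (u in c("utr5", "utr3"))
      if (!is.null(tx[[u]])) tx[[u]] <- sort_spans(tx[[u]])
    if (nrow(tx$exons) == 0) stop("transcript without exons")
    if (any(tx$exons[, 2] <= tx$exons[, 1])) stop("empty or reversed exon span")
    if (nrow(tx$exons) > 1 &&
        any(tx$exons[-1, 1] < tx$exons[-nrow(tx$exons), 2]))
      stop("overlapping exons")
    for (i in seq_len(nrow(tx$cds)))
      if (!any(tx$cds[i, 1] >= tx$exons[, 1] & tx$cds[i, 2] <= tx$exons[, 2]))
        stop("CDS span [", tx$cds[i, 1], ",", tx$cds[i, 2],
             ") not contained in any exon")
    tx
  })
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

sort_spans <- function(m) {
  if (is.null(m)) return(matrix(integer(), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS / UTR features and groups transcripts
#' under their parent genes.  Coordinates are converted from the GFF3
#' 1-based closed convention to the internal 0-based half-open one.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  g$ID <- gff_attr(as.character(g$attributes), "ID")
  g$Parent <- gff_attr(as.character(g$attributes), "Parent")
  g$start0 <- g$start - 1L  # to 0-based half-open
  g$end0 <- g$end

  genes <- g[g$type == "gene", ]
  mrnas <- g[g$type == "mRNA", ]
  if (any(is.na(genes$ID))) stop("gene feature without ID attribute")
  if (any(is.na(mrnas$ID))) stop("mRNA feature without ID attribute")
  bad <- !(mrnas$Parent %in% genes$ID)
  if (any(bad))
    stop("mRNA with unknown parent gene: ",
         paste(mrnas$ID[bad], collapse = ", "))

  parts <- g[g$type %in% c("exon", "CDS", "five_prime_UTR",
                           "three_prime_UTR"), ]
  slot_of <- c(exon = "exons", CDS = "cds",
               five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  tx <- stats::setNames(vector("list", nrow(mrnas)), mrnas$ID)
  for (i in seq_len(nrow(parts))) {
    for (p in strsplit(parts$Parent[i], ",")[[1]]) {
      if (is.na(p) || !(p %in% names(tx)))
        stop("feature with unknown parent transcript: ",
             parts$Parent[i] %||% "<missing>")
      slot <- slot_of[[as.character(parts$type[i])]]
      tx[[p]][[slot]] <- rbind(tx[[p]][[slot]],
                               c(parts$start0[i], parts$end0[i]))
    }
  }

  out <- list()
  for (gid in genes$ID) {
    tids <- mrnas$ID[mrnas$Parent == gid]
    row <- genes[genes$ID == gid, ]
    out[[gid]] <- gene_model(gid, as.character(row$seqid),
                             as.character(row$strand),
                             tx[tids])
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    span <- range(unlist(lapply(gm$transcripts, function(t) t$exons)))
    lines <- c(lines, paste(gm$chrom, "mapkcascades", "gene",
                            span[1] + 1L, span[2], ".", gm$strand, ".",
                            paste0("ID=", gm$gene_id), sep = "\t"))
    for (tid in names(gm$transcripts)) {
      tx <- gm$transcripts[[tid]]
      tspan <- range(tx$exons)
      lines <- c(lines, paste(gm$chrom, "mapkcascades", "mRNA",
                              tspan[1] + 1L, tspan[2], ".", gm$strand, ".",
                              paste0("ID=", tid, ";Parent=", gm$gene_id),
                              sep = "\t"))
      emit <- function(type, spans) {
        if (is.null(spans) || nrow(spans) == 0) return(character())
        paste(gm$chrom, "mapkcascades", type, spans[, 1] + 1L, spans[, 2],
              ".", gm$strand, ".", paste0("Parent=", tid), sep = "\t")
      }
      lines <- c(lines, emit("exon", tx$exons), emit("CDS", tx$cds),
                 emit("five_prime_UTR", tx$utr5),
                 emit("three_prime_UTR", tx$utr3))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix is a TSV whose first column holds gene ids and remaining
#' columns one sample each; the metadata TSV maps every sample to its
#' factor levels (first column: sample name).
#'
#' @param path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return list with `values` (numeric matrix, genes x samples) and
#'   `samples` (data.frame of per-sample factors, rownames = sample names).
#' @export
read_expression_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, TRUE)
  if (any(nonnum))
    stop("non-numeric expression value(s) in column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  values <- as.matrix(vals)
  rownames(values) <- genes

  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  rownames(meta) <- as.character(meta[[1]])
  meta <- meta[, -1, drop = FALSE]
  missing <- setdiff(colnames(values), rownames(meta))
  if (length(missing))
    stop("sample(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  list(values = values, samples = meta[colnames(values), , drop = FALSE])
}

#' Write an expression matrix and its sample metadata
#'
#' @param values numeric matrix, genes x samples.
#' @param samples data.frame of per-sample factors, rownames = sample names.
#' @param path output path for the matrix TSV.
#' @param metadata_path output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(values, samples, path, metadata_path) {
  tab <- data.frame(gene = rownames(values), values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = rownames(samples), samples, check.names = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
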