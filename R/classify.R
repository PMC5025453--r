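AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Kinase-domain signature set
#'
#' The three degenerate signature motifs that distinguish the MAPKKK
#' subfamilies inside the kinase domain.  Notation: `[XY]` is an
#' alternation, `x` a wildcard matching any residue.
#'
#' * ZIK:  `GTPEFMAPE[LV][YF]`
#' * MEKK: `G[TS]Px[FW]MAPEV`
#' * Raf:  `GTxx[WY]MAPE`
#'
#' @return named character vector of signature patterns.
#' @export
kinase_signatures <- function() {
  c(ZIK = "GTPEFMAPE[LV][YF]",
    MEKK = "G[TS]Px[FW]MAPEV",
    Raf = "GTxx[WY]MAPE")
}

# Parse a signature pattern into a list of per-position allowed residue sets.
parse_signature <- function(pattern) {
  out <- list()
  i <- 1L
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (chars[j] != "]") { set <- c(set, chars[j]); j <- j + 1L }
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "x") {
      out[[length(out) + 1L]] <- AA_ALPHABET
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

signature_regex <- function(pattern) {
  sets <- parse_signature(pattern)
  paste0(vapply(sets, function(s)
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]"),
    ""), collapse = "")
}

#' Scan a protein for kinase-domain signature motifs
#'
#' Finds every (possibly overlapping) occurrence of each subfamily
#' signature in an amino-acid sequence.
#'
#' @param sequence amino-acid sequence (single string, standard 20 letters).
#' @param signatures named patterns as returned by [kinase_signatures()].
#' @return data.frame with columns `subfamily`, `position` (0-based),
#'   `match`, sorted by position then subfamily.
#' @examples
#' scan_kinase_signature("AAGTPEFMAPELYAA")
#' @export
scan_kinase_signature <- function(sequence, signatures = kinase_signatures()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop("invalid residue character(s): ", paste(unique(bad), collapse = ", "))
  hits <- list()
  for (fam in names(signatures)) {
    rx <- paste0("(?=(", signature_regex(signatures[[fam]]), "))")
    m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    if (m[1] != -1) {
      k <- length(parse_signature(signatures[[fam]]))
      starts <- as.integer(m) - 1L  # 0-based
      hits[[fam]] <- data.frame(
        subfamily = fam, position = starts,
        match = substring(sequence, starts + 1L, starts + k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(hits, list(data.frame(
    subfamily = character(), position = integer(), match = character(),
    stringsAsFactors = FALSE))))
  out <- out[order(out$position, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a MAPKKK subfamily from signature hits and domain position
#'
#' The signature motif alone is not sufficient: the Raf consensus also
#' occurs in receptor-like kinases, so subfamily calls additionally
#' require the subfamily's characteristic kinase-domain position.
#' ZIK proteins carry the ZIK signature and an N-terminal kinase domain;
#' Raf proteins carry the Raf signature, a C-terminal kinase domain and a
#' long N-terminal regulatory region; MEKK proteins carry the MEKK
#' signature at any domain position.  Precedence ZIK > MEKK > Raf resolves
#' the rare case where one sequence matches several patterns.
#'
#' @param record list with at least `sequence` and `kinase_domain`
#'   (integer c(start, end), 0-based half-open span within the protein).
#' @param hits signature hits from [scan_kinase_signature()]; computed
#'   from `record$sequence` when omitted.
#' @param zik_max_nter maximum N-terminal flank (residues) for a domain to
#'   count as N-terminal.
#' @param raf_min_nter_frac minimum N-terminal flank, as a fraction of the
#'   protein length, for a "long N-terminal regulatory region".
#' @param exclude ids (or a logical) marking known receptor-like kinases to
#'   force to `"unclassified"`.
#' @return one of `"MEKK"`, `"Raf"`, `"ZIK"`, `"unclassified"`.
#' @export
classify_subfamily <- function(record, hits = NULL,
                               zik_max_nter = 60L,
                               raf_min_nter_frac = 0.25,
                               exclude = character()) {
  stopifnot(!is.null(record$kinase_domain))
  if (!is.null(record$id) && record$id %in% exclude) return("unclassified")
  if (is.null(hits)) hits <- scan_kinase_signature(record$sequence)
  len <- nchar(record$sequence)
  dom <- as.integer(record$kinase_domain)
  stopifnot(dom[1] >= 0, dom[1] < dom[2], dom[2] <= len)
  n_ter <- dom[1]
  c_ter <- len - dom[2]
  has <- function(fam) fam %in% hits$subfamily
  if (has("ZIK") && n_ter <= zik_max_nter) return("ZIK")
  if (has("MEKK")) return("MEKK")
  if (has("Raf") && c_ter < n_ter && n_ter >= raf_min_nter_frac * len)
    return("Raf")
  "unclassified"
}

# Average residue masses (Da) and Bjellqvist-style pK values used for the
# theoretical MW and pI.  MW = sum of residue masses + one water.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153
PK_TABLE <- c(nterm = 7.5, cterm = 3.55,
              D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
              H = 5.98, K = 10.0, R = 12.0)

protein_net_charge <- function(counts, ph) {
  pos <- c(nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
           H = unname(counts["H"]))
  neg <- c(cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  q <- 0
  for (g in names(pos))
    q <- q + pos[[g]] / (1 + 10^(ph - PK_TABLE[[g]]))
  for (g in names(neg))
    q <- q - neg[[g]] / (1 + 10^(PK_TABLE[[g]] - ph))
  q
}

#' Theoretical molecular weight and isoelectric point
#'
#' MW is the sum of average residue masses plus one water molecule,
#' reported in kilodaltons.  pI is the root of the Henderson-Hasselbalch
#' net-charge function under the documented pK table, found by bisection
#' on pH 0-14.
#'
#' @param sequence amino-acid sequence without ambiguity codes.
#' @param tol bisection tolerance on pH.
#' @return list with `mw_kda` and `pi`.
#' @examples
#' protein_features("GG")$mw_kda * 1000  # 132.12 Da
#' @export
protein_features <- function(sequence, tol = 1e-6) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad))
    stop("invalid residue character(s): ", paste(unique(bad), collapse = ", "))
  counts <- table(factor(chars, levels = AA_ALPHABET))
  mw <- sum(AA_MASS[names(counts)] * as.numeric(counts)) + WATER_MASS
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  list(mw_kda = mw / 1000, pi = (lo + hi) / 2)
}
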