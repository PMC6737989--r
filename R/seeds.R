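rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' @param x RNA sequence (A/C/G/U, uppercase).
#' @return the reverse complement, 5' to 3'.
#' @export
reverse_complement_rna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(rna_complement[chars])), collapse = "")
}

normalize_rna <- function(seq, what = "sequence") {
  s <- toupper(chartr("Tt", "Uu", seq))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("non-nucleotide symbol '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  s
}

#' Canonical seed-site strings for a miRNA
#'
#' The seed region is miRNA nucleotides 2-8 (5' end). Canonical target
#' sites, written 5' to 3' on the target, are: `8mer` = Watson-Crick
#' reverse complement of positions 2-8 followed by an A opposite position
#' 1; `7mer-m8` = reverse complement of positions 2-8; `7mer-A1` = reverse
#' complement of positions 2-7 followed by an A. No G:U pairing is allowed
#' in the seed match.
#'
#' @param mirna_seq mature miRNA sequence, 5' to 3', length >= 8.
#' @return named character vector with elements `site8`, `site7m8`,
#'   `site7a1`.
#' @export
seed_site_strings <- function(mirna_seq) {
  m <- normalize_rna(mirna_seq, "miRNA")
  if (nchar(m) < 8L) stop("miRNA must be at least 8 nt", call. = FALSE)
  rc28 <- reverse_complement_rna(substr(m, 2L, 8L))
  rc27 <- reverse_complement_rna(substr(m, 2L, 7L))
  c(site8 = paste0(rc28, "A"),
    site7m8 = rc28,
    site7a1 = paste0(rc27, "A"))
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Scans every UTR position for the three canonical site types and reports
#' each site once with its highest tier (8mer > 7mer-m8 > 7mer-A1).
#' Positions are 0-based offsets of the site's 5'-most target nucleotide;
#' `span_start`/`span_end` delimit the matched span as a 0-based half-open
#' interval (8 nt for 8mer, 7 nt otherwise).
#'
#' @param mirna_seq mature miRNA sequence, 5' to 3' (length >= 8).
#' @param utr_seq target 3'UTR sequence, 5' to 3'. Both sequences are
#'   normalized to uppercase RNA; non-nucleotide symbols are an error
#'   naming the position.
#' @return data.frame with columns `utr_position`, `site_type`
#'   (`8mer`, `7mer-m8`, `7mer-A1`), `span_start`, `span_end`.
#' @export
find_seed_sites <- function(mirna_seq, utr_seq) {
  sites <- seed_site_strings(mirna_seq)
  utr <- normalize_rna(utr_seq, "UTR")
  L <- nchar(utr)
  empty <- data.frame(utr_position = integer(0), site_type = character(0),
                      span_start = integer(0), span_end = integer(0),
                      stringsAsFactors = FALSE)
  if (L < 7L) return(empty)
  starts7 <- seq_len(L - 6L)
  win7 <- substring(utr, starts7, starts7 + 6L)
  win8 <- substring(utr, starts7, starts7 + 7L)  # short tail windows never match
  is8 <- win8 == sites[["site8"]]
  is7m8 <- win7 == sites[["site7m8"]]
  is7a1 <- win7 == sites[["site7a1"]]
  type <- ifelse(is8, "8mer",
                 ifelse(is7m8, "7mer-m8",
                        ifelse(is7a1, "7mer-A1", NA_character_)))
  hit <- which(!is.na(type))
  if (length(hit) == 0L) return(empty)
  span <- ifelse(type[hit] == "8mer", 8L, 7L)
  data.frame(utr_position = starts7[hit] - 1L,
             site_type = type[hit],
             span_start = starts7[hit] - 1L,
             span_end = starts7[hit] - 1L + span,
             row.names = NULL, stringsAsFactors = FALSE)
}
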