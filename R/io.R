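#' Read a count matrix from TSV
#'
#' Expects a header row of sample names and a first column of feature IDs.
#' Values must be numeric and non-negative. Feature IDs and sample names
#' must be unique; duplicates and malformed cells are hard errors that name
#' the offending entry.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with feature IDs as rownames and sample names as
#'   colnames. A header-only file yields a valid zero-row matrix.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("count matrix file has no columns", call. = FALSE)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0L) {
    stop("duplicate sample name(s) in ", path, ": ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !is.na(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at row %d (feature %s), column %s",
                   col[bad[1L]], bad[1L], ids[bad[1L]], samples[j]),
           call. = FALSE)
    }
    neg <- which(val < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative value %s at row %d (feature %s), column %s",
                   col[neg[1L]], neg[1L], ids[neg[1L]], samples[j]),
           call. = FALSE)
    }
    m[, j] <- val
  }
  m
}

#' Write a numeric matrix as TSV
#'
#' Full-precision serialization (`%.15g`) so that a read/write round trip
#' preserves IDs exactly and numeric values to at least 12 significant
#' digits.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the feature-ID column.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(mat, path, id_column = "feature_id") {
  mat <- expr_values(mat)
  body <- apply(mat, 2L, function(col) sprintf("%.15g", col))
  if (nrow(mat) == 1L) body <- matrix(body, nrow = 1L)
  if (nrow(mat) == 0L) body <- matrix(character(0), nrow = 0L, ncol = ncol(mat))
  df <- data.frame(rownames(mat), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic feature annotation from GTF
#'
#' Parses rows of feature type `gene` and `miRNA` from a 9-column GTF
#' (1-based, inclusive coordinates on disk). Internally all intervals are
#' converted to 0-based half-open. The per-miRNA genomic copy count is the
#' number of loci sharing the same miRNA name.
#'
#' @param path path to a GTF file.
#' @return a `feature_annotation` data.frame with columns `feature_id`,
#'   `type`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `copy_count`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in data_idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated columns, found %d",
                   i, length(fields)), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(fields[4L]))
    e <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("malformed GTF line %d: non-integer coordinates", i),
           call. = FALSE)
    }
    if (e < s) {
      stop(sprintf("malformed GTF line %d: end (%d) < start (%d)", i, e, s),
           call. = FALSE)
    }
    if (!fields[7L] %in% c("+", "-")) {
      stop(sprintf("malformed GTF line %d: unknown strand symbol '%s'",
                   i, fields[7L]), call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("gene", "miRNA")
  gr <- gr[keep]
  ann <- data.frame(
    feature_id = as.character(gr$gene_id),
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$copy_count <- 1L
  is_mir <- ann$type == "miRNA"
  if (any(is_mir)) {
    tab <- table(ann$feature_id[is_mir])
    ann$copy_count[is_mir] <- as.integer(tab[ann$feature_id[is_mir]])
  }
  class(ann) <- c("feature_annotation", "data.frame")
  ann
}

#' Write feature annotation as GTF
#'
#' Converts internal 0-based half-open intervals back to the 1-based
#' inclusive GTF convention.
#'
#' @param ann a `feature_annotation` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation <- function(ann, path) {
  lines <- sprintf("%s\tmiratlas\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                   ann$chrom, ann$type, ann$start + 1L, ann$end,
                   ann$strand, ann$feature_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read named nucleotide sequences from FASTA
#'
#' Sequences are normalized to an uppercase RNA alphabet (T is rewritten
#' to U).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, 5' to 3'.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", as.character(ss))
  seqs <- toupper(seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write named nucleotide sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a stage result table with fixed formatting
#'
#' Numeric columns are serialized with fixed 6-decimal formatting, except
#' correlation columns (`r`, `r_stages`, `correlation`) which carry 7
#' decimals. Integer-valued columns are left untouched.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (nm in colnames(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      digits <- if (nm %in% c("r", "r_stages", "correlation")) 7L else 6L
      fmt <- paste0("%.", digits, "f")
      txt <- ifelse(is.na(col), "NA", sprintf(fmt, col))
      out[[nm]] <- txt
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
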