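#' Construct a genome set
#'
#' A genome set is the universe all coordinates in the package refer to: an
#' ordered collection of named scaffold sequences over the alphabet ACGTN.
#'
#' @param seqs named character vector of nucleotide sequences (A/C/G/T/N,
#'   upper case).
#' @return an object of class `genome_set` (a named character vector).
#' @export
genome_set <- function(seqs) {
  if (length(seqs) == 0) stop("a genome set needs at least one scaffold")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("all scaffolds must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate scaffold names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("scaffolds contain letters outside ACGTN: ",
         paste(nm[bad], collapse = ", "))
  }
  structure(as.character(seqs), names = nm, class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set with", length(x), "scaffolds,",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Scaffold lengths of a genome set
#' @param genome a [genome_set()].
#' @return named integer vector of lengths in bp.
#' @export
scaffold_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read a FASTA file into a genome set
#'
#' Lower case is folded to upper case; letters outside ACGTN (IUPAC
#' ambiguity codes and anything else) are folded to N, with the number of
#' substitutions reported. Duplicate record names and empty files are
#' errors.
#'
#' @param path path to a FASTA file.
#' @return a [genome_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(recs))
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    message(n_bad, " non-ACGTN letters folded to N in ", path)
  }
  genome_set(setNames(seqs, nm))
}

#' Write a genome set to FASTA
#' @param genome a [genome_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(as.character(genome), names(genome)))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Construct a feature table
#'
#' The internal annotation container: one row per feature, coordinates
#' 0-based half-open. `kind` is free-form but the pipeline uses `gene`,
#' `TE`, `LTR_element`, `LTR_5p`, `LTR_3p` and `exchange_segment`.
#'
#' @param scaffold,start,end,strand,kind,id vectors of equal length;
#'   `strand` one of `+`, `-`, `.`.
#' @param check_unique_id reject duplicate ids within a kind.
#' @return a data.frame of class `feature_table`.
#' @export
feature_table <- function(scaffold, start, end, strand = ".",
                          kind = "feature", id = NULL,
                          check_unique_id = TRUE) {
  n <- length(scaffold)
  if (is.null(id)) id <- sprintf("%s_%06d", kind, seq_len(max(n, 1)))[seq_len(n)]
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   kind = rep_len(as.character(kind), n),
                   id = as.character(id), stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(df$start < 0) || any(df$end <= df$start)) {
      stop("features must satisfy 0 <= start < end")
    }
    if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    if (check_unique_id) {
      dup <- unsplit(lapply(split(df$id, df$kind), duplicated), df$kind)
      if (any(dup)) {
        stop("duplicate feature ids within a kind: ",
             paste(unique(df$id[dup]), collapse = ", "))
      }
    }
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read features from GFF3 or BED
#'
#' Coordinates are normalized to the internal 0-based half-open convention:
#' a GFF3 record `start=s, end=e` (1-based closed) becomes `(s-1, e)`; BED
#' records are already half-open and pass through. Records whose interval
#' is empty after normalization are rejected with a warning. If
#' `scaffold_lengths` is supplied, features extending past the end of their
#' scaffold are clipped (with a warning) and features on unknown scaffolds
#' are dropped.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param scaffold_lengths optional named vector of scaffold lengths used
#'   for clipping.
#' @return a [feature_table()]. For GFF3, `kind` is the `type` column and
#'   `id` the `ID` attribute (falling back to `Name`, then a constructed
#'   id); for BED, `kind` is `"feature"` and `id` the name column.
#' @export
read_features <- function(path, dialect = c("gff3", "bed"),
                          scaffold_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    id <- if (!is.null(md$ID)) as.character(md$ID) else rep(NA, length(gr))
    if (!is.null(md$Name)) id <- ifelse(is.na(id), as.character(md$Name), id)
    id[is.na(id)] <- sprintf("feature_%06d", which(is.na(id)))
    df <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      kind = as.character(md$type), id = id, stringsAsFactors = FALSE)
  } else {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(raw) < 3) stop("BED needs at least 3 columns")
    df <- data.frame(
      scaffold = as.character(raw[[1]]),
      start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
      strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
      kind = "feature",
      id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
        sprintf("feature_%06d", seq_len(nrow(raw))),
      stringsAsFactors = FALSE)
  }
  bad <- df$end <= df$start | df$start < 0
  if (any(bad)) {
    warning(sum(bad), " records with empty or negative intervals rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (!is.null(scaffold_lengths)) {
    known <- df$scaffold %in% names(scaffold_lengths)
    if (any(!known)) {
      warning(sum(!known), " records on unknown scaffolds dropped")
      df <- df[known, , drop = FALSE]
    }
    lim <- as.numeric(scaffold_lengths[df$scaffold])
    over <- df$end > lim
    if (any(over)) {
      warning(sum(over), " records clipped to scaffold length")
      df$end[over] <- lim[over]
    }
  }
  feature_table(df$scaffold, df$start, df$end, df$strand, df$kind, df$id,
                check_unique_id = FALSE)
}

#' Write a feature table to GFF3 or BED
#'
#' The inverse coordinate shift of [read_features()] is applied for GFF3.
#'
#' @param features a [feature_table()].
#' @param path output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    strand <- sub("^\\.$", "*", features$strand)
    gr <- GenomicRanges::GRanges(
      seqnames = features$scaffold,
      ranges = IRanges::IRanges(start = features$start + 1,
                                end = features$end),
      strand = strand)
    S4Vectors::mcols(gr)$type <- features$kind
    S4Vectors::mcols(gr)$ID <- features$id
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    out <- data.frame(features$scaffold, format(features$start, scientific = FALSE, trim = TRUE),
                      format(features$end, scientific = FALSE, trim = TRUE),
                      features$id, 0, features$strand)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a PAF alignment file (minimap2 dialect)
#'
#' Only the 12 mandatory columns are used; cg/extra tags are ignored.
#' Coordinates are 0-based half-open as in the format itself.
#'
#' @param path PAF file.
#' @return data.frame with columns `query, qlen, qstart, qend, strand,
#'   target, tlen, tstart, tend, nmatch, alen, mapq`.
#' @export
read_paf <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 12) stop("not a PAF file: ", path)
  df <- data.frame(
    query = raw[[1]], qlen = as.numeric(raw[[2]]),
    qstart = as.numeric(raw[[3]]), qend = as.numeric(raw[[4]]),
    strand = raw[[5]], target = raw[[6]], tlen = as.numeric(raw[[7]]),
    tstart = as.numeric(raw[[8]]), tend = as.numeric(raw[[9]]),
    nmatch = as.numeric(raw[[10]]), alen = as.numeric(raw[[11]]),
    mapq = as.numeric(raw[[12]]), stringsAsFactors = FALSE)
  ok <- df$qstart >= 0 & df$qstart < df$qend & df$qend <= df$qlen &
    df$tstart >= 0 & df$tstart < df$tend & df$tend <= df$tlen &
    df$nmatch <= df$alen
  if (any(!ok)) {
    warning(sum(!ok), " malformed PAF records rejected")
    df <- df[ok, , drop = FALSE]
  }
  df
}

#' Write PAF records
#' @param paf data.frame as returned by [read_paf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  cols <- c("query", "qlen", "qstart", "qend", "strand", "target", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  out <- paf[, cols]
  for (i in c(2:4, 7:12)) out[[i]] <- format(out[[i]], scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Estimate a 2C value from flow-cytometry fluorescence
#'
#' The 2C DNA content of a sample is the 2C value of an internal standard
#' scaled by the ratio of mean FL2-A fluorescence of the sample to that of
#' the standard.
#'
#' @param fl2a_sample,fl2a_standard mean FL2-A fluorescence of the sample
#'   and of the internal standard (arbitrary units, strictly positive).
#' @param standard_2c known 2C value of the standard, in pg (e.g. 1.96 for
#'   tomato, 9.09 for pea).
#' @return estimated 2C value in pg.
#' @export
estimate_2c <- function(fl2a_sample, fl2a_standard, standard_2c) {
  vals <- c(fl2a_sample, fl2a_standard, standard_2c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all flow-cytometry inputs must be strictly positive")
  }
  standard_2c * fl2a_sample / fl2a_standard
}

#' Haploid genome size from a 2C value
#'
#' Halves the 2C content and converts pg to Mbp. The default conversion of
#' 978 Mbp per pg is the standard DNA mass-to-length constant.
#'
#' @param two_c 2C value in pg.
#' @param conversion Mbp per pg.
#' @return haploid genome size in Mbp.
#' @export
haploid_size_mbp <- function(two_c, conversion = 978) {
  if (!is.numeric(two_c) || any(!is.finite(two_c)) || any(two_c <= 0)) {
    stop("two_c must be strictly positive")
  }
  if (conversion <= 0) stop("conversion must be strictly positive")
  two_c / 2 * conversion
}
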