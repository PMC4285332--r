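# Sequence and table IO. FASTA/FASTQ parsing is delegated to Biostrings;
# a light pre-validation pass supplies line-numbered parse errors for the
# malformed inputs Biostrings reports less specifically.

.nonEmptyLines <- function(lines) which(nzchar(trimws(lines)))

.validateFasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[startsWith(trimws(lines), ";")] <- "" # classic FASTA comments
  idx <- .nonEmptyLines(lines)
  if (!length(idx)) return(0L)
  prev_header <- NA_integer_
  has_seq <- FALSE
  ids <- character()
  for (i in idx) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) < 2)
        stop(sprintf("FASTA parse error at line %d: empty header", i))
      if (!is.na(prev_header) && !has_seq)
        stop(sprintf("FASTA parse error at line %d: record has no sequence",
                     prev_header))
      ids <- c(ids, sub("\\s.*$", "", substring(ln, 2)))
      prev_header <- i
      has_seq <- FALSE
    } else {
      if (is.na(prev_header))
        stop(sprintf("FASTA parse error at line %d: sequence before header", i))
      has_seq <- TRUE
    }
  }
  if (!is.na(prev_header) && !has_seq)
    stop(sprintf("FASTA parse error at line %d: record has no sequence",
                 prev_header))
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicated record id '",
         ids[anyDuplicated(ids)], "'")
  length(ids)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; ids are the header text
#' up to the first whitespace and must be unique within the file.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of uppercase sequences (empty for an
#'   empty file).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n <- .validateFasta(path)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(trimws(lines), ";"))) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(lines[!startsWith(trimws(lines), ";")], tmp)
    path <- tmp
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("\\s", "", as.character(x)))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or `XStringSet`) of sequences.
#' @param path output path.
#' @param header optional metadata comment lines (written with a leading
#'   semicolon, ignored by [readFasta()]).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path, header = NULL) {
  nm <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), nm)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0(";", header), con)
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

.validateFastq <- function(lines) {
  idx <- .nonEmptyLines(lines)
  if (!length(idx)) return(0L)
  if (length(idx) %% 4 != 0)
    stop(sprintf("FASTQ parse error at line %d: truncated record",
                 idx[length(idx)]))
  n <- length(idx) / 4
  for (k in seq_len(n)) {
    h <- idx[4 * k - 3]; s <- idx[4 * k - 2]; p <- idx[4 * k - 1]; q <- idx[4 * k]
    if (!startsWith(lines[h], "@"))
      stop(sprintf("FASTQ parse error at line %d: expected '@' header", h))
    if (!startsWith(lines[p], "+"))
      stop(sprintf("FASTQ parse error at line %d: expected '+' separator", p))
    if (nchar(trimws(lines[s])) != nchar(trimws(lines[q])))
      stop(sprintf(
        "FASTQ parse error at line %d: sequence/quality length mismatch", q))
    if (nchar(trimws(lines[s])) == 0)
      stop(sprintf("FASTQ parse error at line %d: empty sequence", s))
  }
  n
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a 4-line-per-record FASTQ file.
#' @return A list with `seq` (named character vector, uppercase) and `qual`
#'   (list of integer Phred scores, same names and lengths).
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- .validateFastq(lines)
  if (n == 0L)
    return(list(seq = stats::setNames(character(0), character(0)),
                qual = list()))
  idx <- .nonEmptyLines(lines)
  ids <- sub("\\s.*$", "", substring(trimws(lines[idx[seq(1, 4 * n, by = 4)]]), 2))
  seqs <- toupper(trimws(lines[idx[seq(2, 4 * n, by = 4)]]))
  quals <- trimws(lines[idx[seq(4, 4 * n, by = 4)]])
  if (anyDuplicated(ids))
    stop("FASTQ parse error: duplicated record id '", ids[anyDuplicated(ids)], "'")
  qint <- lapply(quals, function(q) as.integer(utf8ToInt(q)) - 33L)
  names(qint) <- ids
  list(seq = stats::setNames(seqs, ids), qual = qint)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param qual optional list of integer quality vectors matching `seqs`;
#'   defaults to a constant Phred 40.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(seqs, path, qual = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    qstr <- if (is.null(qual)) {
      vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    } else {
      vapply(qual, function(q) intToUtf8(q + 33L), character(1))
    }
    writeLines(paste0("@", names(seqs), "\n", unname(seqs), "\n+\n", qstr), con)
  }
  invisible(path)
}

#' Read a sample/barcode/primer mapping table
#'
#' Tab-separated with a header line and columns `sample`, `barcode`,
#' `fwd_primer`, `rev_primer`. Barcodes must be unique and of equal length;
#' sample ids must be unique. Primers may carry IUPAC degeneracies.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
readMapping <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validateMapping(m)
}

#' Validate (and normalize) a mapping table
#'
#' @param m data.frame with columns `sample`, `barcode`, `fwd_primer`,
#'   `rev_primer`.
#' @return The normalized data.frame (sequences uppercased).
#' @export
validateMapping <- function(m) {
  need <- c("sample", "barcode", "fwd_primer", "rev_primer")
  if (!all(need %in% names(m)))
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(m)) stop("mapping table is empty")
  m$sample <- as.character(m$sample)
  for (col in c("barcode", "fwd_primer", "rev_primer"))
    m[[col]] <- toupper(as.character(m[[col]]))
  if (anyDuplicated(m$sample))
    stop("duplicate sample id in mapping: ", m$sample[anyDuplicated(m$sample)])
  if (anyDuplicated(m$barcode))
    stop("duplicate barcode in mapping: ", m$barcode[anyDuplicated(m$barcode)])
  if (length(unique(nchar(m$barcode))) != 1)
    stop("all barcodes must have equal length")
  m
}

#' Write a mapping table
#' @param m mapping data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMapping <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a VariantCounts table as TSV
#'
#' Columns: `variant_id`, `sequence`, then one count column per sample.
#' Rows follow the canonical order (descending total, then lexicographic),
#' so output is bit-reproducible; the round trip through
#' [readCountTable()] is lossless.
#'
#' @param x A [VariantCounts-class] object.
#' @param path output path.
#' @param header optional comment lines prefixed with `#`.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(x, path, header = NULL) {
  stopifnot(is(x, "VariantCounts"))
  df <- data.frame(variant_id = variantIds(x),
                   sequence = x@sequences,
                   stringsAsFactors = FALSE)
  cm <- countMatrix(x)
  for (s in colnames(cm)) df[[s]] <- cm[, s]
  if (!nrow(df))
    df <- data.frame(variant_id = character(0), sequence = character(0))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VariantCounts table written by [writeCountTable()]
#' @param path path to the TSV file.
#' @return A [VariantCounts-class] object.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("variant_id", "sequence") %in% names(df)))
    stop("count table must have variant_id and sequence columns")
  samples <- setdiff(names(df), c("variant_id", "sequence"))
  if (!nrow(df)) {
    cm <- matrix(integer(0), nrow = 0, ncol = length(samples),
                 dimnames = list(NULL, samples))
    return(new("VariantCounts", sequences = character(0), counts = cm))
  }
  cm <- as.matrix(df[, samples, drop = FALSE])
  variantCounts(df$sequence, cm)
}

#' Construct a reference database of annotated ITS2 types
#'
#' @param type_name character vector of type labels (e.g. "A1", "C1h").
#' @param seq character vector of nucleotide sequences (IUPAC letters kept).
#' @param source_tag character vector (recycled) identifying the source set.
#' @return A data.frame of class `ReferenceDb`.
#' @export
referenceDb <- function(type_name, seq, source_tag = "USER") {
  db <- data.frame(type_name = as.character(type_name),
                   seq = toupper(as.character(seq)),
                   source_tag = rep_len(as.character(source_tag),
                                        length(type_name)),
                   stringsAsFactors = FALSE)
  if (!nrow(db)) stop("reference database must be non-empty")
  if (any(!nzchar(db$seq))) stop("reference sequences must be non-empty")
  key <- paste(db$type_name, db$source_tag)
  if (anyDuplicated(key))
    stop("duplicate type_name+source_tag in reference database: ",
         key[anyDuplicated(key)])
  structure(db, class = c("ReferenceDb", "data.frame"))
}

#' Read a reference database from FASTA
#'
#' Headers are parsed as `>type_name[ source_tag]`.
#'
#' @param path path to the FASTA file.
#' @param default_source source tag used when the header has none.
#' @return A `ReferenceDb` data.frame.
#' @export
readReferenceFasta <- function(path, default_source = "USER") {
  if (!file.exists(path)) stop("no such file: ", path)
  .validateFasta(path)
  x <- Biostrings::readBStringSet(path)
  full <- names(x)
  type <- sub("\\s.*$", "", full)
  src <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), default_source)
  referenceDb(type, as.character(x), src)
}

#' Write a reference database to FASTA
#' @param db A `ReferenceDb` data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeReferenceFasta <- function(db, path) {
  writeFasta(stats::setNames(db$seq, paste(db$type_name, db$source_tag)), path)
}
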