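# Pairwise global alignment and uncorrected genetic distance — the metric
# under both clustering tiers and the intragenomic-diversity statistics.

#' Global pairwise alignment (affine gaps, deterministic traceback)
#'
#' Optimal Needleman-Wunsch global alignment under affine gap scoring (a gap
#' of length k costs `gap_open + k * gap_extend`). Ties in the traceback are
#' broken deterministically: diagonal, then up (gap in `b`), then left, so
#' output is bit-stable.
#'
#' @param a,b non-empty nucleotide strings.
#' @param params an [alignmentParams()].
#' @return A list with aligned strings `a` and `b` (equal length, `-` for
#'   gaps) and the alignment `score`.
#' @export
globalAlign <- function(a, b, params = alignmentParams()) {
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  cpp_nw_align(a, b, params$match, params$mismatch, params$gap_open,
               params$gap_extend)
}

#' Uncorrected (p-) distance of an aligned pair
#'
#' Fraction of differing positions between two aligned sequences without
#' evolutionary-model correction. Under the default [gapPolicy()] each
#' maximal internal gap run contributes one difference and one comparable
#' position, and terminal gap columns are excluded.
#'
#' @param aligned_a,aligned_b equal-length aligned strings (gaps as `-`).
#' @param policy a [gapPolicy()].
#' @return A fraction in \[0, 1\].
#' @export
uncorrectedDistance <- function(aligned_a, aligned_b, policy = gapPolicy()) {
  A <- toupper(as.character(aligned_a)[1])
  B <- toupper(as.character(aligned_b)[1])
  if (nchar(A) != nchar(B)) stop("aligned sequences must have equal length")
  if (identical(A, B)) return(0)
  ca <- strsplit(A, "")[[1]]; cb <- strsplit(B, "")[[1]]
  L <- length(ca)
  start <- 1L; end <- L
  if (policy$ignore_terminal_gaps) {
    while (start <= L && (ca[start] == "-" || cb[start] == "-")) start <- start + 1L
    while (end >= 1L && (ca[end] == "-" || cb[end] == "-")) end <- end - 1L
  }
  diff <- 0; pos <- 0
  i <- start
  while (i <= end) {
    ga <- ca[i] == "-"; gb <- cb[i] == "-"
    if (!ga && !gb) {
      pos <- pos + 1
      if (ca[i] != cb[i]) diff <- diff + 1
      i <- i + 1L
    } else if (policy$gap_run_counts_as == "one") {
      gapped <- if (ga) ca else cb
      k <- i
      while (k <= end && gapped[k] == "-") k <- k + 1L
      diff <- diff + 1; pos <- pos + 1
      i <- k
    } else {
      diff <- diff + 1; pos <- pos + 1
      i <- i + 1L
    }
  }
  if (pos == 0) stop("no comparable positions between aligned sequences")
  diff / pos
}

#' Pairwise uncorrected distance of two unaligned sequences
#'
#' Convenience wrapper: align with [globalAlign()], then count with the
#' stated [gapPolicy()]. Identical strings short-circuit to 0.
#'
#' @param a,b nucleotide strings.
#' @param params an [alignmentParams()].
#' @param policy a [gapPolicy()].
#' @return A fraction in \[0, 1\].
#' @export
pairwiseDistance <- function(a, b, params = alignmentParams(),
                             policy = gapPolicy()) {
  d <- cpp_pair_distance(toupper(as.character(a)[1]),
                         toupper(as.character(b)[1]),
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend,
                         policy$gap_run_counts_as == "one",
                         policy$ignore_terminal_gaps)
  if (is.na(d)) stop("no comparable positions between aligned sequences")
  d
}

#' All-pairs uncorrected distance matrix
#'
#' @param x A [VariantCounts-class] table, or a (named) character vector of
#'   sequences.
#' @param params an [alignmentParams()].
#' @param policy a [gapPolicy()].
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   variant id (or sequence names).
#' @export
distanceMatrix <- function(x, params = alignmentParams(), policy = gapPolicy()) {
  if (is(x, "VariantCounts")) {
    seqs <- x@sequences
    labels <- variantIds(x)
  } else {
    seqs <- toupper(as.character(x))
    labels <- if (!is.null(names(x))) names(x) else
      sprintf("s%04d", seq_along(seqs))
  }
  if (!length(seqs)) stop("distance matrix needs at least one sequence")
  dm <- cpp_distance_matrix(seqs, params$match, params$mismatch,
                            params$gap_open, params$gap_extend,
                            policy$gap_run_counts_as == "one",
                            policy$ignore_terminal_gaps)
  if (any(is.na(dm)))
    stop("no comparable positions for at least one sequence pair")
  dimnames(dm) <- list(labels, labels)
  dm
}

#' Write a distance matrix
#'
#' @param dm symmetric labelled matrix from [distanceMatrix()].
#' @param path output path.
#' @param format `"square"` (phylip-style TSV with a leading count line) or
#'   `"sparse"` (three columns id1, id2, dist over unique pairs).
#' @return Invisibly, `path`.
#' @export
writeDistanceMatrix <- function(dm, path, format = c("square", "sparse")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "square") {
    writeLines(as.character(nrow(dm)), con)
    rows <- vapply(seq_len(nrow(dm)), function(i) {
      paste(c(rownames(dm)[i], format(dm[i, ], digits = 6, trim = TRUE)),
            collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  } else {
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(dm)[idx[, 1]],
                     id2 = colnames(dm)[idx[, 2]],
                     dist = dm[idx])
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
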