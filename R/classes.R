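# Core S4 containers: dereplicated variant counts and OTU partitions.

#' VariantCounts: dereplicated unique sequences with per-sample counts
#'
#' Holds the result of collapsing identical reads ("unique.seqs"-style
#' dereplication): one row per distinct sequence variant, one column per
#' sample. Rows are kept in a canonical order (descending total count,
#' ties broken by the lexicographically smaller sequence) so that all
#' derived outputs are bit-reproducible.
#'
#' @slot sequences character vector of uppercase nucleotide strings
#'   (A/C/G/T/N), one per variant, unique.
#' @slot counts integer matrix, variants x samples; rownames are stable
#'   variant ids, colnames are sample ids.
#' @export
setClass("VariantCounts", slots = c(sequences = "character", counts = "matrix"))

setValidity("VariantCounts", function(object) {
  msgs <- character()
  cm <- object@counts
  if (nrow(cm) != length(object@sequences))
    msgs <- c(msgs, "count matrix rows must match number of sequences")
  if (length(object@sequences) && anyDuplicated(object@sequences))
    msgs <- c(msgs, "sequences must be unique")
  if (length(object@sequences) &&
      any(grepl("[^ACGTN]", object@sequences)))
    msgs <- c(msgs, "sequences must be over {A,C,G,T,N}")
  if (is.null(colnames(cm)) && ncol(cm) > 0)
    msgs <- c(msgs, "count matrix must have sample names")
  if (ncol(cm) && anyDuplicated(colnames(cm)))
    msgs <- c(msgs, "sample ids must be unique")
  if (nrow(cm) && (is.null(rownames(cm)) || anyDuplicated(rownames(cm))))
    msgs <- c(msgs, "variant ids must be present and unique")
  if (length(cm) && (any(is.na(cm)) || any(cm < 0)))
    msgs <- c(msgs, "counts must be non-negative")
  if (nrow(cm) && any(rowSums(cm) < 1))
    msgs <- c(msgs, "every variant must have total count >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VariantCounts table
#'
#' Canonicalizes the variant order (descending total, then lexicographic by
#' sequence) and assigns stable variant ids.
#'
#' @param sequences character vector of nucleotide strings.
#' @param counts numeric matrix with one row per sequence and one column per
#'   sample (colnames = sample ids), or a vector for a single sample.
#' @param sample A sample id used when `counts` is a vector.
#' @return A [VariantCounts-class] object.
#' @export
variantCounts <- function(sequences, counts, sample = "sample1") {
  if (is.null(dim(counts))) {
    counts <- matrix(as.numeric(counts), ncol = 1,
                     dimnames = list(NULL, sample))
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  sequences <- toupper(as.character(sequences))
  if (length(sequences)) {
    ord <- order(-rowSums(counts), sequences)
    sequences <- sequences[ord]
    counts <- counts[ord, , drop = FALSE]
    rownames(counts) <- sprintf("v%05d", seq_along(sequences))
  }
  new("VariantCounts", sequences = sequences, counts = counts)
}

#' @describeIn VariantCounts-class Number of distinct variants.
#' @param x,object A `VariantCounts` object.
#' @export
nVariants <- function(x) length(x@sequences)

#' @describeIn VariantCounts-class Variant ids (stable row labels).
#' @export
variantIds <- function(x) rownames(x@counts)

#' @describeIn VariantCounts-class Variant nucleotide sequences, named by id.
#' @export
variantSequences <- function(x) stats::setNames(x@sequences, variantIds(x))

#' @describeIn VariantCounts-class Integer count matrix (variants x samples).
#' @export
countMatrix <- function(x) x@counts

#' @describeIn VariantCounts-class Total read count per variant, named by id.
#' @export
variantTotals <- function(x) {
  stats::setNames(as.integer(rowSums(x@counts)), variantIds(x))
}

#' @describeIn VariantCounts-class Sample ids.
#' @export
sampleIds <- function(x) colnames(x@counts)

#' @rdname VariantCounts-class
#' @param i,j variant / sample subscripts.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "VariantCounts", function(x, i, j, ..., drop = FALSE) {
  cm <- x@counts
  sq <- x@sequences
  if (!missing(i)) {
    cm <- cm[i, , drop = FALSE]
    sq <- sq[if (is.character(i)) match(i, rownames(x@counts)) else i]
  }
  if (!missing(j)) cm <- cm[, j, drop = FALSE]
  keep <- rowSums(cm) >= 1
  new("VariantCounts", sequences = sq[keep], counts = cm[keep, , drop = FALSE])
})

setMethod("show", "VariantCounts", function(object) {
  cat(sprintf("VariantCounts: %d variants x %d samples, %d reads total\n",
              nVariants(object), ncol(object@counts), sum(object@counts)))
  if (nVariants(object)) {
    tot <- variantTotals(object)
    top <- utils::head(tot, 3)
    cat("  top variants:",
        paste(sprintf("%s (n=%d, %dnt)", names(top), top,
                      nchar(object@sequences[seq_along(top)])),
              collapse = ", "),
        "\n")
  }
  invisible(object)
})

#' OtuPartition: assignment of variants to clusters at a stated cut-off
#'
#' @slot cutoff numeric distance threshold at which the partition was formed.
#' @slot membership named integer vector mapping variant id -> cluster index
#'   (1..k, numbered by first appearance in label order).
#' @slot representatives character vector of representative variant ids, one
#'   per cluster (NA when not yet picked).
#' @slot annotation data.frame with one row per cluster (columns `type_name`,
#'   `pct_identity`, `tie`) or zero rows when unannotated.
#' @export
setClass("OtuPartition",
         slots = c(cutoff = "numeric", membership = "integer",
                   representatives = "character", annotation = "data.frame"))

setValidity("OtuPartition", function(object) {
  msgs <- character()
  k <- if (length(object@membership)) max(object@membership) else 0L
  if (length(object@membership)) {
    if (is.null(names(object@membership)))
      msgs <- c(msgs, "membership must be named by variant id")
    if (!all(sort(unique(object@membership)) == seq_len(k)))
      msgs <- c(msgs, "cluster indices must be 1..k with no gaps")
  }
  if (length(object@representatives) && length(object@representatives) != k)
    msgs <- c(msgs, "one representative per cluster required")
  if (nrow(object@annotation) && nrow(object@annotation) != k)
    msgs <- c(msgs, "one annotation row per cluster required")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OtuPartition-class Number of clusters.
#' @param x,object An `OtuPartition`.
#' @export
nOtus <- function(x) if (length(x@membership)) max(x@membership) else 0L

#' @describeIn OtuPartition-class Member variant ids per cluster (a list).
#' @export
otuMembers <- function(x) {
  split(names(x@membership), x@membership)
}

#' @describeIn OtuPartition-class The clustering cut-off used.
#' @export
otuCutoff <- function(x) x@cutoff

#' @describeIn OtuPartition-class Cluster membership vector (named integers).
#' @export
otuMembership <- function(x) x@membership

#' @describeIn OtuPartition-class Representative variant ids (or NA).
#' @export
otuRepresentatives <- function(x) x@representatives

setMethod("show", "OtuPartition", function(object) {
  sizes <- tabulate(object@membership, nbins = nOtus(object))
  cat(sprintf("OtuPartition: %d cluster(s) over %d variants at cut-off %.4g\n",
              nOtus(object), length(object@membership), object@cutoff))
  if (nOtus(object))
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(object)
})

newOtuPartition <- function(cutoff, membership,
                            representatives = rep(NA_character_,
                                                  if (length(membership)) max(membership) else 0L),
                            annotation = data.frame()) {
  new("OtuPartition", cutoff = as.numeric(cutoff),
      membership = membership, representatives = representatives,
      annotation = annotation)
}
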