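# Read-level stages: demultiplexing, primer trimming, quality filtering,
# dereplication, singleton removal and the simplified chimera flagger.

.DISCARD_REASONS <- c("barcode", "fwd_primer", "rev_primer_missing",
                      "ambiguity", "homopolymer", "length")

# as.character drops names (e.g. off an XStringSet); keep them
.asChar <- function(x) {
  nm <- names(x)
  s <- as.character(x)
  names(s) <- nm
  s
}

# Coerce reads to uppercase character; IUPAC ambiguity letters other than N
# are normalized to N (the ambiguity filter discards such reads anyway).
.asReadChar <- function(reads) {
  s <- toupper(.asChar(reads))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) s[bad] <- gsub("[^ACGTN]", "N", s[bad])
  if (is.null(names(s)) && length(s))
    names(s) <- sprintf("read%06d", seq_along(s))
  s
}

# IUPAC-aware per-position mismatch count between equal-length read segment
# and primer (degeneracies expanded on the primer side only).
.iupacMismatches <- function(segments, primer) {
  pl <- nchar(primer)
  pchars <- strsplit(primer, "")[[1]]
  allowed <- lapply(pchars, function(ch) {
    exp <- Biostrings::IUPAC_CODE_MAP[[ch]]
    if (is.null(exp)) ch else strsplit(exp, "")[[1]]
  })
  segmat <- matrix(unlist(strsplit(segments, "")), nrow = pl)
  mism <- integer(length(segments))
  for (k in seq_len(pl))
    mism <- mism + !(segmat[k, ] %in% allowed[[k]])
  mism
}

.emptyReport <- function(samples) {
  df <- data.frame(sample = c(samples, "unassigned"),
                   input = 0L, kept = 0L, stringsAsFactors = FALSE)
  for (r in .DISCARD_REASONS) df[[r]] <- 0L
  df
}

#' Demultiplex reads by barcode and trim barcode + forward primer
#'
#' Barcodes are matched 5'-anchored by Hamming distance (no indels); the
#' forward primer immediately follows and is matched with IUPAC expansion on
#' the primer side. Reads failing either screen are discarded with a reason.
#' Kept reads have barcode and forward primer removed from the 5' end.
#'
#' @param reads named character vector (or `XStringSet`) of raw reads.
#' @param mapping mapping data.frame (see [readMapping()]).
#' @param policy a [filterPolicy()].
#' @return A list with `samples` (named list of per-sample read vectors) and
#'   `report` (per-sample kept/discarded counts keyed by reason).
#' @export
demultiplex <- function(reads, mapping, policy = filterPolicy()) {
  mapping <- validateMapping(mapping)
  reads <- .asReadChar(reads)
  bl <- nchar(mapping$barcode[1])
  report <- .emptyReport(mapping$sample)
  rownames(report) <- report$sample
  out <- stats::setNames(vector("list", nrow(mapping)), mapping$sample)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (!length(reads)) {
    return(list(samples = lapply(out, function(x) x), report = report))
  }
  report["unassigned", "input"] <- length(reads)

  # barcode assignment
  bc <- substr(reads, 1, bl)
  too_short <- nchar(reads) < bl
  if (policy$max_barcode_mismatch == 0L) {
    sidx <- match(bc, mapping$barcode)
  } else {
    sidx <- rep(NA_integer_, length(reads))
    for (r in which(!too_short)) {
      d <- .hamming(bc[r], mapping$barcode)
      j <- which(d <= policy$max_barcode_mismatch)
      if (length(j)) sidx[r] <- j[which.min(d[j])]
    }
  }
  sidx[too_short] <- NA_integer_
  bad_bc <- is.na(sidx)
  report["unassigned", "barcode"] <- sum(bad_bc)

  kept <- !bad_bc
  # forward primer per assigned sample
  for (i in seq_len(nrow(mapping))) {
    sel <- which(kept & sidx == i)
    if (!length(sel)) next
    primer <- mapping$fwd_primer[i]
    pl <- nchar(primer)
    short <- nchar(reads[sel]) < bl + pl
    seg <- substr(reads[sel[!short]], bl + 1, bl + pl)
    mism <- if (length(seg)) .iupacMismatches(seg, primer) else integer(0)
    fail <- logical(length(sel))
    fail[short] <- TRUE
    fail[!short] <- mism > policy$max_fwd_primer_mismatch
    report[i, "fwd_primer"] <- sum(fail)
    report[i, "input"] <- report[i, "input"] + length(sel)
    ok <- sel[!fail]
    trimmed <- substring(reads[ok], bl + pl + 1)
    names(trimmed) <- names(reads)[ok]
    out[[i]] <- trimmed
    report[i, "kept"] <- length(ok)
  }
  # move per-sample inputs out of the unassigned pool
  report["unassigned", "input"] <- sum(bad_bc)
  list(samples = out, report = report)
}

.hamming <- function(a, b) {
  # a: single string; b: vector of equal-length strings
  achars <- strsplit(a, "")[[1]]
  vapply(strsplit(b, ""), function(bc) sum(achars != bc), integer(1))
}

#' Remove the reverse primer from the 3' end of reads
#'
#' Scans for the best occurrence of the primer (a full occurrence anywhere,
#' or a primer prefix overlapping the read's 3' end by at least
#' `min_overlap` nt) and removes it together with everything downstream when
#' the mismatch rate does not exceed `error_rate` (substitutions only).
#'
#' @param reads named character vector of reads.
#' @param rev_primer the primer sequence as it appears at the read 3' end.
#' @param error_rate maximum mismatch rate (default 0.15).
#' @param min_overlap minimum 3'-overlap in nt (default 8).
#' @return A list with `seq` (trimmed reads) and `trimmed` (logical flags).
#' @export
trimReversePrimer <- function(reads, rev_primer, error_rate = 0.15,
                              min_overlap = 8L) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  reads <- toupper(.asChar(reads))
  if (!length(reads)) return(list(seq = reads, trimmed = logical(0)))
  res <- cpp_trim_reverse(reads, toupper(rev_primer), error_rate,
                          as.integer(min_overlap))
  list(seq = stats::setNames(as.character(res$seq), names(reads)),
       trimmed = as.logical(res$trimmed))
}

#' Sequence-based quality filter
#'
#' Applies, in order: ambiguity screen (more than `max_ambiguous` N bases),
#' homopolymer screen (any single-base run strictly longer than
#' `max_homopolymer`), and length screen (shorter than `min_length`). The
#' first failing rule is reported.
#'
#' @param reads named character vector of demultiplexed, trimmed reads.
#' @param policy a [filterPolicy()].
#' @return A list with `kept` (named character vector) and `reasons` (named
#'   character vector over discarded reads).
#' @export
qualityFilter <- function(reads, policy = filterPolicy()) {
  reads <- toupper(.asChar(reads))
  if (!length(reads))
    return(list(kept = reads, reasons = stats::setNames(character(0), NULL)))
  nN <- nchar(reads) - nchar(gsub("N", "", reads, fixed = TRUE))
  k <- policy$max_homopolymer + 1L
  runpat <- paste0(sprintf("%s{%d,}", c("A", "C", "G", "T", "N"), k),
                   collapse = "|")
  has_run <- grepl(runpat, reads)
  reason <- rep(NA_character_, length(reads))
  reason[nchar(reads) < policy$min_length] <- "length"
  reason[has_run] <- "homopolymer"
  reason[nN > policy$max_ambiguous] <- "ambiguity"
  keep <- is.na(reason)
  list(kept = reads[keep],
       reasons = stats::setNames(reason[!keep], names(reads)[!keep]))
}

#' Collapse identical reads into unique variants with per-sample counts
#'
#' @param samples named list mapping sample id to a character vector of
#'   filtered reads.
#' @return A [VariantCounts-class] table (canonically ordered). Empty input
#'   yields an empty table.
#' @export
dereplicate <- function(samples) {
  samples <- lapply(samples, function(x) toupper(as.character(unname(x))))
  ids <- names(samples)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("dereplicate needs a named list of per-sample reads")
  all_seq <- unlist(samples, use.names = FALSE)
  if (!length(all_seq)) {
    cm <- matrix(integer(0), nrow = 0, ncol = length(ids),
                 dimnames = list(NULL, ids))
    return(new("VariantCounts", sequences = character(0), counts = cm))
  }
  all_sample <- rep(ids, vapply(samples, length, integer(1)))
  tab <- table(factor(all_seq), factor(all_sample, levels = ids))
  cm <- matrix(as.integer(tab), nrow = nrow(tab),
               dimnames = list(NULL, colnames(tab)))
  variantCounts(rownames(tab), cm)
}

#' Remove singletons (variants seen exactly once across the whole data set)
#'
#' @param x A [VariantCounts-class] table.
#' @return The table with all total-count-1 variants removed.
#' @export
removeSingletons <- function(x) {
  stopifnot(is(x, "VariantCounts"))
  if (!nVariants(x)) return(x)
  keep <- variantTotals(x) > 1L
  new("VariantCounts", sequences = x@sequences[keep],
      counts = x@counts[keep, , drop = FALSE])
}

#' Flag and remove likely chimeric variants
#'
#' A deliberately simplified two-parent abundance-skew model: a variant is
#' flagged when some split point yields a 5' segment within 1 mismatch of a
#' variant at least `skew`-fold more abundant and a 3' segment within 1
#' mismatch of a different such variant, while its best single-parent match
#' carries at least 3 mismatches. Checking is pooled across samples by
#' default; with `per_sample = TRUE` each sample's own abundances are used
#' and the union of flags is removed.
#'
#' @param x A [VariantCounts-class] table.
#' @param skew minimum parent/variant abundance ratio (default 2).
#' @param per_sample logical; check per sample instead of pooled.
#' @return A list with `table` (flagged variants removed) and `flagged`
#'   (character vector of removed variant ids).
#' @export
flagChimeras <- function(x, skew = 2, per_sample = FALSE) {
  stopifnot(is(x, "VariantCounts"))
  if (nVariants(x) < 2)
    return(list(table = x, flagged = character(0)))
  seqs <- x@sequences
  if (per_sample) {
    fl <- rep(FALSE, nVariants(x))
    for (s in sampleIds(x)) {
      cnt <- countMatrix(x)[, s]
      pres <- cnt > 0
      if (sum(pres) < 2) next
      f <- cpp_flag_chimeras(seqs[pres], as.numeric(cnt[pres]), skew, 1L, 3L)
      fl[pres] <- fl[pres] | f
    }
  } else {
    fl <- cpp_flag_chimeras(seqs, as.numeric(variantTotals(x)), skew, 1L, 3L)
  }
  flagged <- variantIds(x)[fl]
  tab <- if (any(fl)) {
    new("VariantCounts", sequences = seqs[!fl],
        counts = x@counts[!fl, , drop = FALSE])
  } else x
  list(table = tab, flagged = flagged)
}
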