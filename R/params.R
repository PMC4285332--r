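# Parameter bundles. Plain validated lists, mirroring the filter criteria
# applied to the 454 data (mismatch/ambiguity/homopolymer/length screens)
# and the alignment/distance conventions used throughout.

#' Read-filtering policy
#'
#' Thresholds for demultiplexing and sequence-based quality filtering.
#' Defaults reproduce the published screen: discard reads with any barcode
#' mismatch, more than 2 forward-primer mismatches, any ambiguous base,
#' a homopolymer run longer than 4, or post-trim length below 250 nt; the
#' reverse primer is removed cutadapt-style at an overall error rate of 0.15.
#'
#' @param max_barcode_mismatch integer, maximum barcode Hamming mismatches.
#' @param max_fwd_primer_mismatch integer, maximum forward-primer mismatches
#'   (IUPAC-aware, substitutions only).
#' @param max_ambiguous integer, maximum number of N bases tolerated.
#' @param max_homopolymer integer, longest tolerated single-base run; a run
#'   strictly longer triggers discard.
#' @param min_length integer, minimum post-trim read length.
#' @param rev_primer_error_rate fraction in \[0,1\], maximum mismatch rate for
#'   reverse-primer removal.
#' @param require_rev_primer logical; if TRUE reads without a reverse-primer
#'   hit are discarded (reason `rev_primer_missing`), otherwise kept
#'   untrimmed (the cutadapt default behaviour).
#' @return A named list of class `FilterPolicy`.
#' @export
filterPolicy <- function(max_barcode_mismatch = 0L,
                         max_fwd_primer_mismatch = 2L,
                         max_ambiguous = 0L,
                         max_homopolymer = 4L,
                         min_length = 250L,
                         rev_primer_error_rate = 0.15,
                         require_rev_primer = FALSE) {
  p <- list(max_barcode_mismatch = as.integer(max_barcode_mismatch),
            max_fwd_primer_mismatch = as.integer(max_fwd_primer_mismatch),
            max_ambiguous = as.integer(max_ambiguous),
            max_homopolymer = as.integer(max_homopolymer),
            min_length = as.integer(min_length),
            rev_primer_error_rate = as.numeric(rev_primer_error_rate),
            require_rev_primer = isTRUE(require_rev_primer))
  ints <- c("max_barcode_mismatch", "max_fwd_primer_mismatch",
            "max_ambiguous", "max_homopolymer", "min_length")
  if (any(vapply(p[ints], function(v) is.na(v) || v < 0, logical(1))))
    stop("all FilterPolicy thresholds must be >= 0")
  if (is.na(p$rev_primer_error_rate) || p$rev_primer_error_rate < 0 ||
      p$rev_primer_error_rate > 1)
    stop("rev_primer_error_rate must be in [0,1]")
  structure(p, class = c("FilterPolicy", "list"))
}

#' Pairwise global-alignment scores
#'
#' Affine-gap Needleman-Wunsch scores used for all pairwise alignments. A gap
#' of length k costs `gap_open + k * gap_extend`. Fixed defaults keep output
#' bit-reproducible; they are echoed into all output metadata.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; `mismatch` must
#'   be below `match` and gap penalties negative.
#' @return A named list of class `AlignmentParams`.
#' @export
alignmentParams <- function(match = 2L, mismatch = -2L, gap_open = -4L,
                            gap_extend = -2L) {
  p <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
  if (p$mismatch >= p$match) stop("mismatch score must be below match score")
  if (p$gap_open >= 0 || p$gap_extend >= 0)
    stop("gap penalties must be negative")
  structure(p, class = c("AlignmentParams", "list"))
}

#' Gap handling for uncorrected distances
#'
#' Convention for counting gap columns when turning an aligned pair into an
#' uncorrected (p-) distance. With `gap_run_counts_as = "one"` each maximal
#' internal gap run contributes a single difference and a single comparable
#' position (the default of the distance calculator the field's toolkit
#' applies); with `"each"` every gap column counts. Terminal gap columns are
#' excluded when `ignore_terminal_gaps` is TRUE.
#'
#' @param gap_run_counts_as `"one"` or `"each"`.
#' @param ignore_terminal_gaps logical.
#' @return A named list of class `GapPolicy`.
#' @export
gapPolicy <- function(gap_run_counts_as = c("one", "each"),
                      ignore_terminal_gaps = TRUE) {
  structure(list(gap_run_counts_as = match.arg(gap_run_counts_as),
                 ignore_terminal_gaps = isTRUE(ignore_terminal_gaps)),
            class = c("GapPolicy", "list"))
}

#' Two-tier clustering thresholds
#'
#' @param clade_cutoff distance for clade binning (default 0.15, empirically
#'   separates the deeply divergent symbiont clades).
#' @param otu_cutoff within-clade species/type cut-off (default 0.03, i.e.
#'   97% similarity, the value at which isoclonal-culture variation collapses
#'   into one OTU).
#' @param length_screen_quantile variants shorter than this fraction of their
#'   clade's sequences are discarded (default 0.90).
#' @return A named list of class `PipelineThresholds`.
#' @export
pipelineThresholds <- function(clade_cutoff = 0.15, otu_cutoff = 0.03,
                               length_screen_quantile = 0.90) {
  p <- list(clade_cutoff = as.numeric(clade_cutoff),
            otu_cutoff = as.numeric(otu_cutoff),
            length_screen_quantile = as.numeric(length_screen_quantile))
  if (!(p$otu_cutoff > 0 && p$otu_cutoff < p$clade_cutoff && p$clade_cutoff <= 1))
    stop("need 0 < otu_cutoff < clade_cutoff <= 1")
  if (!(p$length_screen_quantile > 0 && p$length_screen_quantile <= 1))
    stop("length_screen_quantile must be in (0,1]")
  structure(p, class = c("PipelineThresholds", "list"))
}
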