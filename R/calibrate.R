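# Cut-off calibration from isoclonal-culture controls and per-culture
# intragenomic distance statistics.

#' Intragenomic distance statistics for one control culture
#'
#' Restricts a sample to variants represented by at least `min_count` reads
#' in that sample (guarding against contamination and ultralow-abundance
#' copies), computes all pairwise uncorrected distances, and summarizes
#' them. The median of an even number of distances is the midpoint of the
#' two central values.
#'
#' @param x A [VariantCounts-class] table.
#' @param sample sample id present in `x`.
#' @param min_count per-sample minimum read count (default 100).
#' @param params,policy alignment and gap settings.
#' @return A one-row data.frame with `sample_id`, `n_variants_used`,
#'   `mean`, `median`, `minimum`, `maximum`, `range` and `sufficient`.
#'   With fewer than 2 qualifying variants, `sufficient` is FALSE and the
#'   distance summaries are NA (never silent zeros).
#' @export
intragenomicStats <- function(x, sample, min_count = 100,
                              params = alignmentParams(),
                              policy = gapPolicy()) {
  stopifnot(is(x, "VariantCounts"))
  if (!sample %in% sampleIds(x)) stop("unknown sample: ", sample)
  cnt <- countMatrix(x)[, sample]
  qual <- which(cnt >= min_count)
  if (length(qual) < 2) {
    return(data.frame(sample_id = sample, n_variants_used = length(qual),
                      mean = NA_real_, median = NA_real_, minimum = NA_real_,
                      maximum = NA_real_, range = NA_real_,
                      sufficient = FALSE, stringsAsFactors = FALSE))
  }
  dm <- distanceMatrix(x[qual, ], params, policy)
  d <- dm[upper.tri(dm)]
  data.frame(sample_id = sample, n_variants_used = length(qual),
             mean = mean(d), median = stats::median(d), minimum = min(d),
             maximum = max(d), range = max(d) - min(d), sufficient = TRUE,
             stringsAsFactors = FALSE)
}

#' Derive the species/type-level OTU cut-off from control cultures
#'
#' For each candidate cut-off on the grid, every control culture's
#' qualifying variants (per-sample count >= `min_count`) are clustered with
#' [averageNeighborCluster()]; the derived cut-off is the smallest grid
#' value at which every control collapses into exactly one OTU.
#'
#' @param x A [VariantCounts-class] table.
#' @param controls character vector of control sample ids.
#' @param grid ascending candidate cut-offs (default 0.01..0.10).
#' @param min_count per-sample minimum read count (default 100).
#' @param params,policy alignment and gap settings.
#' @return A list of class `CalibrationResult` with `grid`, `otu_counts`
#'   (controls x grid matrix), `derived_cutoff` (NA when no grid value
#'   collapses all controls), `status`, and `degenerate` (controls with < 2
#'   qualifying variants, which trivially give one OTU).
#' @export
deriveSpeciesCutoff <- function(x, controls, grid = seq(0.01, 0.10, by = 0.01),
                                min_count = 100,
                                params = alignmentParams(),
                                policy = gapPolicy()) {
  stopifnot(is(x, "VariantCounts"))
  if (!length(grid)) stop("empty cut-off grid")
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  if (!length(controls)) stop("need at least one control sample")
  missing <- setdiff(controls, sampleIds(x))
  if (length(missing)) stop("unknown control sample: ", missing[1])

  counts <- matrix(NA_integer_, nrow = length(controls), ncol = length(grid),
                   dimnames = list(controls, format(grid, trim = TRUE)))
  degenerate <- character(0)
  for (s in controls) {
    cnt <- countMatrix(x)[, s]
    qual <- which(cnt >= min_count)
    if (length(qual) < 2) {
      degenerate <- c(degenerate, s)
      counts[s, ] <- 1L
      next
    }
    dm <- distanceMatrix(x[qual, ], params, policy)
    counts[s, ] <- vapply(grid, function(g)
      nOtus(averageNeighborCluster(dm, g)), integer(1))
  }
  collapsed <- apply(counts == 1L, 2, all)
  derived <- if (any(collapsed)) grid[which(collapsed)[1]] else NA_real_
  status <- if (length(degenerate) == length(controls)) {
    warning("all controls are degenerate (<2 qualifying variants); ",
            "returning the smallest grid value")
    "degenerate-controls"
  } else if (is.na(derived)) "none in grid" else "ok"
  structure(list(grid = grid, otu_counts = counts, derived_cutoff = derived,
                 status = status, degenerate = degenerate,
                 min_count = min_count),
            class = "CalibrationResult")
}

#' @export
print.CalibrationResult <- function(x, ...) {
  cat("Species/type cut-off calibration\n")
  cat(sprintf("  grid: %s\n", paste(format(x$grid, trim = TRUE), collapse = " ")))
  cat(sprintf("  derived cut-off: %s (%s)\n",
              ifelse(is.na(x$derived_cutoff), "none in grid",
                     format(x$derived_cutoff)), x$status))
  print(x$otu_counts)
  invisible(x)
}

#' Check a candidate clade cut-off against known clade labels
#'
#' Clusters mixed-control variants at each candidate cut-off and reports
#' whether the expected clade partition is recovered exactly (adjusted Rand
#' index of 1 against the truth labels).
#'
#' @param x A [VariantCounts-class] table (or a distance matrix).
#' @param expected named vector of expected clade labels per variant id.
#' @param candidates candidate cut-off values.
#' @param params,policy alignment and gap settings when `x` is a table.
#' @return A data.frame with `candidate`, `n_clusters`, `ari`, `recovered`.
#' @export
cladeCutoffCheck <- function(x, expected, candidates = c(0.10, 0.15, 0.20),
                             params = alignmentParams(), policy = gapPolicy()) {
  dm <- if (is(x, "VariantCounts")) distanceMatrix(x, params, policy) else
    as.matrix(x)
  ids <- rownames(dm)
  if (is.null(names(expected)) || !all(ids %in% names(expected)))
    stop("expected labels must be named by variant id and cover the matrix")
  truth <- expected[ids]
  rows <- lapply(candidates, function(cand) {
    part <- averageNeighborCluster(dm, cand)
    memb <- otuMembership(part)[ids]
    ari <- if (length(unique(memb)) == 1 && length(unique(truth)) == 1) 1 else
      mclust::adjustedRandIndex(memb, truth)
    data.frame(candidate = cand, n_clusters = nOtus(part), ari = ari,
               recovered = abs(ari - 1) < 1e-12)
  })
  do.call(rbind, rows)
}
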