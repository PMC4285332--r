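# Two-tier OTU framework: clade binning at a coarse cut-off, per-clade
# length screen, average-neighbour clustering at the species/type cut-off,
# representative picking and nearest-reference annotation.

#' Average-neighbour (average-linkage) clustering at a cut-off
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the arithmetic mean of all cross-pair distances. Clusters are merged
#' while the smallest average inter-cluster distance does not exceed the
#' cut-off (closed threshold). Built on `stats::hclust(method = "average")`
#' (UPGMA, whose merge heights are exactly those averages and are monotone),
#' cut at the threshold.
#'
#' @param dm symmetric labelled distance matrix (see [distanceMatrix()]).
#' @param cutoff distance threshold; merges with average linkage <= cutoff
#'   are performed.
#' @return An [OtuPartition-class]; clusters are numbered by first
#'   appearance in label order.
#' @export
averageNeighborCluster <- function(dm, cutoff) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n == 0) stop("empty distance matrix")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- sprintf("s%04d", seq_len(n))
  if (n == 1) {
    memb <- stats::setNames(1L, labels)
    return(newOtuPartition(cutoff, memb))
  }
  h <- stats::hclust(stats::as.dist(dm), method = "average")
  # union-find over merges at height <= cutoff (small eps absorbs the
  # floating-point drift of successive Lance-Williams averaging)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cluster_of_merge <- integer(length(h$height))
  for (k in seq_along(h$height)) {
    if (h$height[k] > cutoff + 1e-9) break
    a <- h$merge[k, 1]; b <- h$merge[k, 2]
    ra <- if (a < 0) find(-a) else find(cluster_of_merge[a])
    rb <- if (b < 0) find(-b) else find(cluster_of_merge[b])
    parent[rb] <- ra
    cluster_of_merge[k] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  memb <- stats::setNames(match(roots, unique(roots)), labels)
  newOtuPartition(cutoff, memb)
}

#' Assign variants to clades by coarse clustering
#'
#' Clusters all variants with [averageNeighborCluster()] at the clade
#' cut-off; the resulting clusters become clades, numbered by descending
#' total read count (clade 1 = most reads).
#'
#' @param x A [VariantCounts-class] table.
#' @param dm distance matrix over all variants of `x` (labelled by variant
#'   id); computed from `x` when NULL.
#' @param clade_cutoff distance threshold (default 0.15).
#' @param params,policy alignment and gap settings used when `dm` is NULL.
#' @return A named integer vector: variant id -> clade number.
#' @export
assignClades <- function(x, dm = NULL, clade_cutoff = 0.15,
                         params = alignmentParams(), policy = gapPolicy()) {
  stopifnot(is(x, "VariantCounts"))
  if (is.null(dm)) dm <- distanceMatrix(x, params, policy)
  part <- averageNeighborCluster(dm[variantIds(x), variantIds(x), drop = FALSE],
                                 clade_cutoff)
  memb <- otuMembership(part)
  tot <- variantTotals(x)[names(memb)]
  clade_reads <- tapply(tot, memb, sum)
  ord <- order(-clade_reads, as.integer(names(clade_reads)))
  renum <- stats::setNames(seq_along(ord), names(clade_reads)[ord])
  stats::setNames(as.integer(renum[as.character(memb)]), names(memb))
}

#' Per-clade length screen
#'
#' Discards variants that are shorter than 90% (by default) of the clade's
#' sequences: the threshold is the nearest-rank length at rank
#' `floor((1 - quantile) * n) + 1` of the sorted lengths, and variants
#' strictly shorter than it are discarded.
#'
#' @param x A [VariantCounts-class] table holding one clade's variants.
#' @param quantile fraction (default 0.90).
#' @return A list with `retained` (a `VariantCounts`) and `discarded`
#'   (character vector of variant ids).
#' @export
lengthScreen <- function(x, quantile = 0.90) {
  stopifnot(is(x, "VariantCounts"))
  if (!nVariants(x)) stop("length screen needs at least one variant")
  len <- nchar(x@sequences)
  # small eps guards against 1 - 0.9 = 0.0999... landing below the rank
  thr <- sort(len)[floor((1 - quantile) * length(len) + 1e-9) + 1L]
  drop <- len < thr
  retained <- if (any(drop)) {
    new("VariantCounts", sequences = x@sequences[!drop],
        counts = x@counts[!drop, , drop = FALSE])
  } else x
  list(retained = retained, discarded = variantIds(x)[drop])
}

#' Pick the representative variant of a cluster
#'
#' The member with the highest total read count; ties are broken by the
#' lexicographically smallest sequence.
#'
#' @param x A [VariantCounts-class] table.
#' @param members character vector of member variant ids (default: all).
#' @return A single variant id.
#' @export
pickRepresentative <- function(x, members = variantIds(x)) {
  stopifnot(is(x, "VariantCounts"), length(members) > 0)
  idx <- match(members, variantIds(x))
  if (anyNA(idx)) stop("unknown variant id in cluster members")
  tot <- as.integer(rowSums(x@counts[idx, , drop = FALSE]))
  sq <- x@sequences[idx]
  members[order(-tot, sq)][1]
}

#' Nearest reference in an annotated ITS2 type database
#'
#' Exhaustive global alignment of the query against every database entry;
#' percent identity is `100 * (1 - d)` with `d` the uncorrected distance
#' under the same [gapPolicy()] as all other distances.
#'
#' @param query nucleotide string.
#' @param db a `ReferenceDb` data.frame (see [referenceDb()]).
#' @param params,policy alignment and gap settings.
#' @return A list with `type_name`, `pct_identity` and `tie` (TRUE when a
#'   different type achieves the same identity; the first in database order
#'   is returned).
#' @export
nearestReference <- function(query, db, params = alignmentParams(),
                             policy = gapPolicy()) {
  if (!is.data.frame(db) || !nrow(db)) stop("reference database is empty")
  q <- toupper(as.character(query)[1])
  d <- vapply(db$seq, function(s) {
    cpp_pair_distance(q, s, params$match, params$mismatch, params$gap_open,
                      params$gap_extend, policy$gap_run_counts_as == "one",
                      policy$ignore_terminal_gaps)
  }, numeric(1), USE.NAMES = FALSE)
  best <- which.min(d)
  ident <- 100 * (1 - d)
  tie <- any(abs(ident[-best] - ident[best]) < 1e-9 &
               db$type_name[-best] != db$type_name[best])
  list(type_name = db$type_name[best],
       pct_identity = ident[best],
       tie = isTRUE(tie))
}

.cladeLetter <- function(type_name) sub("^([A-Za-z]+).*$", "\\1", type_name)

#' Run the full OTU-typing pipeline on raw reads
#'
#' Executes demultiplexing, reverse-primer trimming, quality filtering,
#' dereplication, chimera flagging, singleton removal, clade binning,
#' per-clade length screen, within-clade average-neighbour OTU clustering,
#' representative picking and nearest-reference annotation.
#'
#' @param reads named character vector (or `XStringSet`) of raw reads.
#' @param mapping mapping data.frame (see [readMapping()]).
#' @param refdb a `ReferenceDb` data.frame.
#' @param policy a [filterPolicy()].
#' @param thresholds a [pipelineThresholds()].
#' @param params,policy_gap alignment and gap settings.
#' @param chimera_per_sample logical; per-sample chimera checking.
#' @param min_identity minimum percent identity for annotation; below it (or
#'   on an annotation tie) OTUs are labelled `unclassified_<clade>`.
#' @return A list of class `its2Pipeline` with elements `otuTable`
#'   (per-sample read counts per OTU with clade, representative and
#'   annotation), `cladeTable`, `variants` (retained `VariantCounts`),
#'   `cladeAssignment`, `partitions`, `report`, `flaggedChimeras` and
#'   `parameters`.
#' @export
runPipeline <- function(reads, mapping, refdb,
                        policy = filterPolicy(),
                        thresholds = pipelineThresholds(),
                        params = alignmentParams(),
                        policy_gap = gapPolicy(),
                        chimera_per_sample = FALSE,
                        min_identity = 90) {
  dx <- demultiplex(reads, mapping, policy)
  report <- dx$report
  if (!sum(vapply(dx$samples, length, integer(1))))
    stop("pipeline stage demultiplex: no reads retained")

  samples <- dx$samples
  for (i in seq_along(samples)) {
    if (!length(samples[[i]])) next
    rp <- mapping$rev_primer[match(names(samples)[i], mapping$sample)]
    tr <- trimReversePrimer(samples[[i]], rp, policy$rev_primer_error_rate)
    if (policy$require_rev_primer) {
      report[i, "rev_primer_missing"] <- sum(!tr$trimmed)
      report[i, "kept"] <- report[i, "kept"] - sum(!tr$trimmed)
      samples[[i]] <- tr$seq[tr$trimmed]
    } else {
      samples[[i]] <- tr$seq
    }
    qf <- qualityFilter(samples[[i]], policy)
    if (length(qf$reasons)) {
      tb <- table(factor(qf$reasons, levels = .DISCARD_REASONS))
      for (r in names(tb)) report[i, r] <- report[i, r] + as.integer(tb[[r]])
      report[i, "kept"] <- report[i, "kept"] - length(qf$reasons)
    }
    samples[[i]] <- qf$kept
  }
  if (!sum(vapply(samples, length, integer(1))))
    stop("pipeline stage quality_filter: no reads retained")

  vc <- dereplicate(samples)
  ch <- flagChimeras(vc, per_sample = chimera_per_sample)
  vc <- removeSingletons(ch$table)
  if (!nVariants(vc))
    stop("pipeline stage singleton_removal: no variants retained")

  dm <- distanceMatrix(vc, params, policy_gap)
  clades <- assignClades(vc, dm, thresholds$clade_cutoff)

  otu_rows <- list()
  clade_rows <- list()
  partitions <- list()
  retained_ids <- character(0)
  for (cl in sort(unique(clades))) {
    ids <- names(clades)[clades == cl]
    sub <- vc[ids, ]
    scr <- lengthScreen(sub, thresholds$length_screen_quantile)
    sub <- scr$retained
    if (!nVariants(sub)) next
    ids <- variantIds(sub)
    retained_ids <- c(retained_ids, ids)
    sdm <- dm[ids, ids, drop = FALSE]
    part <- averageNeighborCluster(sdm, thresholds$otu_cutoff)
    members <- otuMembers(part)
    reps <- vapply(members, function(m) pickRepresentative(sub, m), character(1))
    ann <- lapply(reps, function(r) {
      nearestReference(variantSequences(sub)[[r]], refdb, params, policy_gap)
    })
    # clade letter from the annotation of the clade's dominant variant
    dom_ann <- ann[[which.max(vapply(members, function(m)
      sum(variantTotals(sub)[m]), numeric(1)))]]
    clade_label <- if (dom_ann$pct_identity >= min_identity && !dom_ann$tie)
      .cladeLetter(dom_ann$type_name) else sprintf("cl%d", cl)

    cm <- countMatrix(sub)
    otu_tot <- vapply(members, function(m) sum(variantTotals(sub)[m]), numeric(1))
    oord <- order(-otu_tot, vapply(members, function(m) min(m), character(1)))
    for (r in seq_along(oord)) {
      k <- oord[r]
      a <- ann[[k]]
      tn <- if (a$pct_identity >= min_identity && !a$tie) a$type_name else
        sprintf("unclassified_%s", clade_label)
      counts <- colSums(cm[members[[k]], , drop = FALSE])
      otu_rows[[length(otu_rows) + 1L]] <- data.frame(
        otu_id = sprintf("OTU%d_%s%.2f", r, clade_label, thresholds$otu_cutoff),
        clade = clade_label,
        n_variants = length(members[[k]]),
        representative_id = reps[[k]],
        type_name = tn,
        pct_identity = round(a$pct_identity, 2),
        t(counts),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    clade_rows[[length(clade_rows) + 1L]] <- data.frame(
      clade = clade_label, n_variants = nVariants(sub),
      n_otus = nOtus(part), t(colSums(cm)),
      check.names = FALSE, stringsAsFactors = FALSE)
    partitions[[clade_label]] <- newOtuPartition(
      thresholds$otu_cutoff, otuMembership(part),
      unname(reps),
      data.frame(type_name = vapply(ann, `[[`, character(1), "type_name"),
                 pct_identity = vapply(ann, `[[`, numeric(1), "pct_identity"),
                 tie = vapply(ann, `[[`, logical(1), "tie"),
                 stringsAsFactors = FALSE))
  }
  if (!length(otu_rows))
    stop("pipeline stage length_screen: no variants retained")
  structure(list(
    otuTable = do.call(rbind, otu_rows),
    cladeTable = do.call(rbind, clade_rows),
    variants = vc,
    cladeAssignment = clades,
    partitions = partitions,
    report = report,
    flaggedChimeras = ch$flagged,
    parameters = list(filter = policy, thresholds = thresholds,
                      alignment = params, gap = policy_gap)),
    class = "its2Pipeline")
}

#' @export
print.its2Pipeline <- function(x, ...) {
  cat(sprintf("ITS2 OTU pipeline result: %d OTU(s) in %d clade(s), %d samples\n",
              nrow(x$otuTable), length(unique(x$otuTable$clade)),
              ncol(countMatrix(x$variants))))
  cat(sprintf("  retained variants: %d; flagged chimeras: %d\n",
              nVariants(x$variants), length(x$flaggedChimeras)))
  print(x$otuTable[, c("otu_id", "clade", "n_variants", "type_name",
                       "pct_identity")], row.names = FALSE)
  invisible(x)
}
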