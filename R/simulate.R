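# Synthetic-data generator. Emulates the genomic and technical structure of
# multicopy ITS2 amplicon data: per-genome long-tail variant abundance (one
# or two dominant rDNA copies plus many rare variants within a few percent
# divergence), deeply divergent clades, per-lineage rDNA copy-number bias,
# and barcoded pyrosequencing-style reads with substitution errors,
# homopolymer indels in runs and chimeras. The generator assumes reads have
# already been flowgram-denoised, so residual error rates are low.

.ITS_FWD_PRIMER <- "GAATTGCAGAACTCCGTG"
.ITS_REV_PRIMER_OLIGO <- "GGGATCCATATGCTTAAGTTCAGCGGGT"

#' Default primers (forward, and reverse as it appears at the read 3' end)
#' @return A list with `fwd` and `rev` primer strings.
#' @export
defaultPrimers <- function() {
  list(fwd = .ITS_FWD_PRIMER,
       rev = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(.ITS_REV_PRIMER_OLIGO))))
}

.maxRun <- function(s) max(rle(strsplit(s, "")[[1]])$lengths)

# Random template with homopolymer runs capped at maxRun (so templates pass
# the homopolymer screen and single substitutions rarely create a run > 4).
.randomTemplate <- function(len, max_run = 3L) {
  bases <- c("A", "C", "G", "T")
  out <- character(len)
  run <- 0L
  prev <- ""
  for (i in seq_len(len)) {
    choices <- if (run >= max_run) setdiff(bases, prev) else bases
    b <- sample(choices, 1)
    run <- if (identical(b, prev)) run + 1L else 1L
    prev <- b
    out[i] <- b
  }
  paste(out, collapse = "")
}

#' Generate divergent clade template sequences
#'
#' Draws one random template per clade (homopolymer runs capped at 3) and
#' rejection-samples until all pairwise uncorrected distances exceed
#' `min_divergence`, matching the deep inter-clade divergence of the system.
#'
#' @param n number of clades.
#' @param length template length in nt (default 330, amplicon-scale).
#' @param min_divergence minimum pairwise distance (default 0.20).
#' @param seed integer seed; RNG state restored afterwards.
#' @return A character vector of templates named by clade letter.
#' @export
simulateCladeTemplates <- function(n, length = 330L, min_divergence = 0.20,
                                   seed = 1) {
  withr::with_seed(seed, {
    tmpl <- character(0)
    while (base::length(tmpl) < n) {
      cand <- .randomTemplate(length)
      ok <- all(vapply(tmpl, function(t)
        pairwiseDistance(cand, t) > min_divergence, logical(1)))
      if (ok) tmpl <- c(tmpl, cand)
    }
    stats::setNames(tmpl, LETTERS[seq_len(n)])
  })
}

#' Specify a genome's rDNA library model
#'
#' @param species_name type label (e.g. "A1"); used for reference annotation.
#' @param clade_label clade letter.
#' @param dominant_seqs one or two dominant ITS2 copies (~300-360 nt).
#' @param n_rare_variants number of rare intragenomic variants.
#' @param max_intra_divergence maximum uncorrected distance of any rare
#'   variant from its dominant copy (default 0.02).
#' @param dominance fraction of rDNA copies that are dominant (default 0.8).
#' @param rdna_copy_weight relative rDNA copy number of this lineage
#'   (default 1); read sampling weight is cell proportion x copy weight.
#' @param rare_decay geometric decay of rare-variant frequencies (default
#'   0.8, which makes the dominant copy ~20-fold more abundant than the
#'   second most common variant).
#' @return A list of class `GenomeModel`.
#' @export
genomeModel <- function(species_name, clade_label, dominant_seqs,
                        n_rare_variants = 29L, max_intra_divergence = 0.02,
                        dominance = 0.8, rdna_copy_weight = 1,
                        rare_decay = 0.8) {
  dominant_seqs <- toupper(as.character(dominant_seqs))
  if (!length(dominant_seqs) || length(dominant_seqs) > 2)
    stop("need 1 or 2 dominant sequences")
  if (dominance <= 0 || dominance > 1) stop("dominance must be in (0,1]")
  if (n_rare_variants > 0 && dominance == 1)
    stop("rare variants require dominance < 1")
  structure(list(species_name = as.character(species_name),
                 clade_label = as.character(clade_label),
                 dominant_seqs = dominant_seqs,
                 n_rare_variants = as.integer(n_rare_variants),
                 max_intra_divergence = as.numeric(max_intra_divergence),
                 dominance = as.numeric(dominance),
                 rdna_copy_weight = as.numeric(rdna_copy_weight),
                 rare_decay = as.numeric(rare_decay)),
            class = c("GenomeModel", "list"))
}

.mutateSeq <- function(seq, n_subs, max_run = 4L) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:50) {
    mut <- chars
    sites <- sample(length(chars), n_subs)
    for (s in sites) mut[s] <- sample(setdiff(bases, chars[s]), 1)
    out <- paste(mut, collapse = "")
    if (.maxRun(out) <= max_run) return(out)
  }
  out
}

#' Simulate a genome's rDNA variant pool
#'
#' The dominant sequence(s) carry the `dominance` fraction of copies (split
#' 2:1 when there are two); rare variants are generated by substituting the
#' dominant copies at up to `max_intra_divergence * length` sites, with
#' geometrically decaying frequencies (a long-tail abundance distribution).
#'
#' @param model a [genomeModel()].
#' @param seed optional integer seed; RNG state restored afterwards.
#' @return A data.frame with `sequence`, `frequency` (summing to 1),
#'   `class` ("dominant"/"rare") and `parent` (index of the dominant copy a
#'   rare variant derives from).
#' @export
simulateRdnaLibrary <- function(model, seed = NULL) {
  run <- function() {
    doms <- model$dominant_seqs
    ndom <- length(doms)
    dom_w <- if (ndom == 2) c(2, 1) / 3 else 1
    nr <- model$n_rare_variants
    seqs <- doms
    parent <- seq_len(ndom)
    cls <- rep("dominant", ndom)
    if (nr > 0) {
      L <- nchar(doms[1])
      max_subs <- max(1L, floor(model$max_intra_divergence * L))
      for (k in seq_len(nr)) {
        p <- sample.int(ndom, 1, prob = dom_w)
        for (attempt in 1:100) {
          ns <- sample.int(max_subs, 1)
          cand <- .mutateSeq(doms[p], ns)
          if (!cand %in% seqs) break
        }
        seqs <- c(seqs, cand)
        parent <- c(parent, p)
        cls <- c(cls, "rare")
      }
    }
    freq <- if (nr > 0) {
      rare_w <- model$rare_decay^(seq_len(nr) - 1)
      c(model$dominance * dom_w,
        (1 - model$dominance) * rare_w / sum(rare_w))
    } else dom_w
    data.frame(sequence = seqs, frequency = freq, class = cls,
               parent = parent, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Specify the read/error model
#'
#' @param barcode sample barcode (prepended to every read).
#' @param fwd_primer,rev_primer primer sequences; `rev_primer` is the
#'   sequence as it appears at the read 3' end.
#' @param substitution_rate per-base substitution error rate (default 2e-4;
#'   the generator emulates denoised pyrosequencing reads).
#' @param homopolymer_indel_rate per-base rate of +/-1 indels inside
#'   homopolymer runs of length >= 3 (default 1e-4).
#' @param chimera_rate fraction of reads formed by splicing two templates.
#' @return A list of class `ReadModel`.
#' @export
readModel <- function(barcode, fwd_primer = defaultPrimers()$fwd,
                      rev_primer = defaultPrimers()$rev,
                      substitution_rate = 2e-4,
                      homopolymer_indel_rate = 1e-4,
                      chimera_rate = 0) {
  rates <- c(substitution_rate, homopolymer_indel_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]")
  structure(list(barcode = toupper(barcode),
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 chimera_rate = chimera_rate),
            class = c("ReadModel", "list"))
}

.homopolymerRuns <- function(chars) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 3L
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Simulate one barcoded amplicon sample
#'
#' Draws reads from the pooled rDNA libraries of the given genomes with
#' sampling weights `cell proportion x rdna_copy_weight`, applies
#' substitution and homopolymer-indel errors, forms chimeras at
#' `chimera_rate` by splicing two distinct templates at a random breakpoint,
#' and wraps each read as `barcode + fwd_primer + insert + rev_primer`.
#'
#' @param sample_id sample name.
#' @param genomes list of [genomeModel()] objects.
#' @param proportions cell proportions (summing to 1).
#' @param n_reads number of reads.
#' @param model a [readModel()].
#' @param seed integer seed; RNG state restored afterwards. Byte-identical
#'   output for identical inputs and seed.
#' @return A list with `reads` (named character vector), `truth`
#'   (data.frame: read_id, species, template_id, n_subs, n_indels,
#'   is_chimera), `templates` (pooled template table with expected read
#'   fractions), `mapping` (one-row mapping data.frame) and `libraries`.
#' @export
simulateSample <- function(sample_id, genomes, proportions, n_reads, model,
                           seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (length(genomes) != length(proportions))
    stop("one proportion per genome required")
  withr::with_seed(seed, {
    libs <- lapply(genomes, simulateRdnaLibrary)
    gw <- proportions * vapply(genomes, `[[`, numeric(1), "rdna_copy_weight")
    gw <- gw / sum(gw)
    pool <- do.call(rbind, lapply(seq_along(genomes), function(g) {
      data.frame(species = genomes[[g]]$species_name,
                 clade = genomes[[g]]$clade_label,
                 sequence = libs[[g]]$sequence,
                 frequency = libs[[g]]$frequency * gw[g],
                 stringsAsFactors = FALSE)
    }))
    pool$template_id <- sprintf("t%03d", seq_len(nrow(pool)))
    tmpl_chars <- strsplit(pool$sequence, "")
    tmpl_runs <- lapply(tmpl_chars, .homopolymerRuns)

    t_idx <- sample.int(nrow(pool), n_reads, replace = TRUE,
                        prob = pool$frequency)
    is_chim <- if (model$chimera_rate > 0)
      stats::runif(n_reads) < model$chimera_rate else rep(FALSE, n_reads)
    bases <- c("A", "C", "G", "T")
    reads <- character(n_reads)
    n_subs <- integer(n_reads)
    n_indels <- integer(n_reads)
    species <- pool$species[t_idx]
    template_id <- pool$template_id[t_idx]
    for (r in seq_len(n_reads)) {
      if (is_chim[r] && nrow(pool) > 1) {
        p2 <- sample.int(nrow(pool), 1, prob = pool$frequency)
        while (p2 == t_idx[r])
          p2 <- sample.int(nrow(pool), 1, prob = pool$frequency)
        c1 <- tmpl_chars[[t_idx[r]]]
        c2 <- tmpl_chars[[p2]]
        cut <- sample(seq(30L, min(length(c1), length(c2)) - 30L), 1)
        chars <- c(c1[seq_len(cut)], c2[(cut + 1):length(c2)])
        species[r] <- "chimera"
        template_id[r] <- paste(pool$template_id[t_idx[r]],
                                pool$template_id[p2], sep = "x")
        runs <- .homopolymerRuns(chars)
      } else {
        chars <- tmpl_chars[[t_idx[r]]]
        runs <- tmpl_runs[[t_idx[r]]]
      }
      ns <- stats::rbinom(1, length(chars), model$substitution_rate)
      if (ns > 0) {
        sites <- sample(length(chars), ns)
        for (s in sites) chars[s] <- sample(setdiff(bases, chars[s]), 1)
      }
      ni <- 0L
      if (model$homopolymer_indel_rate > 0 && nrow(runs)) {
        hit <- stats::runif(nrow(runs)) <
          pmin(1, model$homopolymer_indel_rate * runs$len)
        # process hits right-to-left so earlier run offsets stay valid
        for (h in rev(which(hit))) {
          ni <- ni + 1L
          if (stats::runif(1) < 0.5) {
            chars <- append(chars, runs$base[h], after = runs$start[h])
          } else {
            chars <- chars[-runs$start[h]]
          }
        }
      }
      reads[r] <- paste0(model$barcode, model$fwd_primer,
                         paste(chars, collapse = ""), model$rev_primer)
      n_subs[r] <- ns
      n_indels[r] <- ni
    }
    ids <- sprintf("%s_read%06d", sample_id, seq_len(n_reads))
    list(reads = stats::setNames(reads, ids),
         truth = data.frame(read_id = ids, sample = sample_id,
                            species = species, template_id = template_id,
                            n_subs = n_subs, n_indels = n_indels,
                            is_chimera = is_chim, stringsAsFactors = FALSE),
         templates = pool,
         mapping = data.frame(sample = sample_id, barcode = model$barcode,
                              fwd_primer = model$fwd_primer,
                              rev_primer = model$rev_primer,
                              stringsAsFactors = FALSE),
         libraries = libs)
  })
}

#' Build a reference database from genome models
#'
#' One entry per dominant copy, named by species/type (second dominant
#' copies get a `-2` suffix); the source tag marks entries as synthetic.
#'
#' @param genomes list of [genomeModel()] objects.
#' @return A `ReferenceDb` data.frame.
#' @export
makeReferenceDb <- function(genomes) {
  if (!length(genomes)) stop("need at least one genome")
  names_ <- unlist(lapply(genomes, function(g) {
    if (length(g$dominant_seqs) == 2)
      c(g$species_name, paste0(g$species_name, "-2")) else g$species_name
  }))
  seqs <- unlist(lapply(genomes, `[[`, "dominant_seqs"))
  referenceDb(names_, seqs, source_tag = "SIM")
}

.makeBarcodes <- function(n, length = 8L, seed = 99) {
  withr::with_seed(seed, {
    out <- character(0)
    while (base::length(out) < n) {
      b <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (!b %in% out) out <- c(out, b)
    }
    out
  })
}

#' Simulate a multi-sample sequencing run
#'
#' Convenience wrapper: one [simulateSample()] call per scenario entry with
#' automatically assigned distinct barcodes, a combined mapping table, a
#' pooled read set and a reference database of all dominant copies.
#'
#' @param scenarios named list; each element is a list with `genomes`,
#'   `proportions` and `n_reads` (element name = sample id).
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @param substitution_rate,homopolymer_indel_rate,chimera_rate error rates
#'   passed to [readModel()].
#' @return A list with `reads`, `mapping`, `truth`, `refdb` and `samples`
#'   (the per-sample simulation results).
#' @export
simulateExperiment <- function(scenarios, seed = 1,
                               substitution_rate = 2e-4,
                               homopolymer_indel_rate = 1e-4,
                               chimera_rate = 0) {
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be a named list (names = sample ids)")
  bcs <- .makeBarcodes(length(scenarios), seed = seed %% 100000L + 7L)
  res <- vector("list", length(scenarios))
  names(res) <- names(scenarios)
  all_genomes <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    rm_ <- readModel(barcode = bcs[i],
                     substitution_rate = substitution_rate,
                     homopolymer_indel_rate = homopolymer_indel_rate,
                     chimera_rate = chimera_rate)
    res[[i]] <- simulateSample(names(scenarios)[i], sc$genomes,
                               sc$proportions, sc$n_reads, rm_,
                               seed = (seed * 131L + i) %% .Machine$integer.max)
    for (g in sc$genomes)
      if (!g$species_name %in% vapply(all_genomes, `[[`, character(1),
                                      "species_name"))
        all_genomes[[length(all_genomes) + 1L]] <- g
  }
  list(reads = do.call(c, unname(lapply(res, `[[`, "reads"))),
       mapping = do.call(rbind, lapply(res, `[[`, "mapping")),
       truth = do.call(rbind, c(lapply(res, `[[`, "truth"),
                                list(make.row.names = FALSE))),
       refdb = makeReferenceDb(all_genomes),
       samples = res)
}
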