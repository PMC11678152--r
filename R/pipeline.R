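#' Comparative sRNA discovery over a strain family
#'
#' Runs the genomic arm of the pipeline: IGR extraction on the reference and
#' every comparator strain, reciprocal-best-hit conservation calling, family
#' alignment of each conserved IGR (reference row first), and the windowed
#' comparative structure screen.
#'
#' @param reference reference `annotation_set`.
#' @param strains named list of comparator `annotation_set`s.
#' @param min_strains conservation threshold (default 4).
#' @param seed RNG seed for the screen's shuffles (local).
#' @param ... screen parameters passed to [scan_igr_windows()].
#' @return list with `igrs` (reference `igr_set`), `rbbh`, `conservation`
#'   (see [call_conserved()]), `families` (named list of alignments for the
#'   conserved IGRs) and `calls` (merged positive structure calls).
#' @export
discover_srnas <- function(reference, strains, min_strains = 4L, seed = NULL,
                           ...) {
  igrs_ref <- extract_igrs(reference)
  igrs_oth <- lapply(strains, extract_igrs)
  rbbh <- find_rbbh_pairs(igrs_ref, igrs_oth)
  cons <- call_conserved(igrs_ref, rbbh, min_strains = min_strains)
  conserved_ids <- cons$records$igr_id[cons$records$conserved]
  families <- stats::setNames(lapply(conserved_ids, function(id) {
    partners <- list()
    for (g in names(rbbh)) {
      h <- rbbh[[g]]
      row <- h[h$query == id, , drop = FALSE]
      if (!nrow(row)) next
      seq <- igrs_oth[[g]]$sequence[igrs_oth[[g]]$id == row$subject[1]]
      if (row$strand[1] == "-") seq <- revcomp(seq)
      partners[[g]] <- seq
    }
    align_family(igrs_ref$sequence[igrs_ref$id == id],
                 unlist(partners))
  }), conserved_ids)
  calls <- with_seed(seed, {
    cl <- lapply(conserved_ids, function(id)
      scan_igr_windows(families[[id]], igr_id = id, ...))
    do.call(rbind, cl)
  })
  if (is.null(calls)) calls <- empty_structure_calls()
  list(igrs = igrs_ref, rbbh = rbbh, conservation = cons,
       families = families, calls = calls)
}

#' Expression arm of the pipeline on a simulated (or real) count set
#'
#' Reliability-filters novel transcripts, tests differential expression of
#' sRNAs and mRNAs against the reference time point, computes
#' opposite-expression pairs, and calls consensus targets on the OE pairs.
#'
#' @param sim a count set as returned by [simulate_counts()] (elements
#'   `counts`, `design`, `categories`, `srna_seqs`, `mrna_seqs`).
#' @param reference reference time point.
#' @param min_samples,min_reads reliability-filter thresholds.
#' @param energy_cut,prob_cut,min_oe target-calling thresholds.
#' @param n_null null size for the interaction probability.
#' @param seed RNG seed (local).
#' @param ... duplex parameters passed down to [call_targets()].
#' @return list with `reliable` (filter table), `de_srna`, `de_mrna`, `oe`
#'   and `targets`.
#' @export
profile_srnas <- function(sim, reference = "24h", min_samples = 10L,
                          min_reads = 20L, energy_cut = -20, prob_cut = 0.5,
                          min_oe = 2L, n_null = 100L, seed = NULL, ...) {
  counts <- sim$counts
  srna_ids <- names(sim$srna_seqs)
  mrna_ids <- names(sim$mrna_seqs)
  novel <- rownames(counts)[sim$categories[rownames(counts)] == "novel"]
  # the reliability filter runs against the broad library compendium when
  # one is available, not against the growth-curve samples alone
  filter_counts <- sim$compendium %||% counts
  reliable <- filter_putative_srnas(filter_counts[novel, , drop = FALSE],
                                    min_samples, min_reads)
  kept_srnas <- intersect(
    reliable$transcript_id[reliable$reliable_srna], srna_ids)
  de_srna <- de_test(counts[kept_srnas, , drop = FALSE], sim$design,
                     reference = reference)
  de_mrna <- de_test(counts[mrna_ids, , drop = FALSE], sim$design,
                     reference = reference)
  oe <- opposite_expression(de_srna, de_mrna, min_contrasts = min_oe)
  targets <- if (nrow(oe)) {
    call_targets(oe[, c("srna_id", "mrna_id")], sim$srna_seqs,
                 sim$mrna_seqs, oe = oe, energy_cut = energy_cut,
                 prob_cut = prob_cut, n_null = n_null, seed = seed,
                 min_oe = min_oe, ...)
  } else {
    call_targets(data.frame(srna_id = character(), mrna_id = character()),
                 sim$srna_seqs, sim$mrna_seqs, oe = oe)
  }
  list(reliable = reliable, de_srna = de_srna, de_mrna = de_mrna, oe = oe,
       targets = targets)
}
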