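#' Transcripts-per-million normalization
#'
#' `rate = count / length` per transcript; each sample column is scaled so
#' that its TPM values sum to one million. An all-zero sample column stays
#' all zero (with a warning).
#'
#' @param counts numeric matrix, transcripts x samples (row names = ids).
#' @param lengths per-transcript lengths (nt), `>= 1`.
#' @return TPM matrix with the same dimensions and dimnames.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths >= 1),
            all(counts >= 0))
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0))
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts)[denom == 0], collapse = ", "))
  tpm <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  tpm[, denom == 0] <- 0
  tpm
}

#' Cumulative expression-breadth distribution
#'
#' Fraction of transcripts expressed (`count > 0`) in at least `k` samples,
#' for `k = 1..n_samples`; per category when `categories` is given. The
#' curves are non-increasing in `k` by construction.
#'
#' @param counts counts matrix, transcripts x samples.
#' @param categories optional per-transcript category labels; curves are then
#'   returned for `"all"` plus each category present.
#' @return a `data.frame` with columns category, k, fraction.
#' @export
expression_breadth <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  nexp <- rowSums(counts > 0)
  curve <- function(idx) {
    if (!length(idx)) return(rep(NA_real_, n))
    vapply(seq_len(n), function(k) mean(nexp[idx] >= k), numeric(1))
  }
  groups <- list(all = seq_len(nrow(counts)))
  if (!is.null(categories)) {
    stopifnot(length(categories) == nrow(counts))
    groups <- c(groups, split(seq_len(nrow(counts)), categories))
  }
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(category = g, k = seq_len(n), fraction = curve(groups[[g]]),
               stringsAsFactors = FALSE)
  }))
}

#' Reliability filter for putative sRNAs
#'
#' Retains a transcript when it has at least `min_reads` reads in each of at
#' least `min_samples` samples (defaults 20 reads / 10 samples). The filter
#' is monotone: raising either threshold never grows the retained set.
#'
#' @param counts counts matrix, transcripts x samples (row names = ids).
#' @param min_samples minimum number of qualifying samples.
#' @param min_reads minimum reads per qualifying sample.
#' @return a `data.frame`: transcript_id, n_samples_passing, reliable_srna.
#' @export
filter_putative_srnas <- function(counts, min_samples = 10L, min_reads = 20L) {
  counts <- as.matrix(counts)
  ids <- rownames(counts) %||% paste0("t", seq_len(nrow(counts)))
  n_pass <- rowSums(counts >= min_reads)
  data.frame(transcript_id = ids, n_samples_passing = as.integer(n_pass),
             reliable_srna = n_pass >= min_samples, stringsAsFactors = FALSE)
}

#' Per-transcript expression summary
#'
#' @param counts counts matrix, transcripts x samples.
#' @param lengths per-transcript lengths (nt).
#' @param categories per-transcript labels over
#'   `{CDS, tRNA, rRNA, antisense, novel}`.
#' @param min_samples,min_reads reliability thresholds applied to
#'   `novel`-category transcripts (see [filter_putative_srnas()]).
#' @return `data.frame`: transcript_id, category, length,
#'   n_samples_expressed, max_tpm, reliable_srna.
#' @export
transcript_expression <- function(counts, lengths, categories,
                                  min_samples = 10L, min_reads = 20L) {
  counts <- as.matrix(counts)
  tpm <- compute_tpm(counts, lengths)
  filt <- filter_putative_srnas(counts, min_samples, min_reads)
  data.frame(
    transcript_id = filt$transcript_id,
    category = categories,
    length = lengths,
    n_samples_expressed = as.integer(rowSums(counts > 0)),
    max_tpm = apply(tpm, 1, max),
    reliable_srna = filt$reliable_srna & categories == "novel",
    stringsAsFactors = FALSE
  )
}

#' Operon statistics from transcription-unit gene counts
#'
#' Transcription units are classified as single genes, gene pairs, or
#' multi-gene operons (three or more genes). The mean number of genes per
#' operon averages over units with at least two genes (single genes are not
#' operons); it is `NA` when there are none.
#'
#' @param tus a `data.frame` with columns `tu_id` and `gene_ids`
#'   (comma-separated) and optionally `replicon`, or an integer vector of TU
#'   sizes.
#' @return a list with `classes` (per-replicon counts of single/pair/multi),
#'   `size_histogram`, `mean_genes_per_operon`, and `max_genes`.
#' @export
classify_operons <- function(tus) {
  if (is.numeric(tus)) {
    sizes <- as.integer(tus)
    replicon <- rep("all", length(sizes))
  } else {
    stopifnot(all(c("tu_id", "gene_ids") %in% names(tus)))
    sizes <- lengths(strsplit(as.character(tus$gene_ids), ",", fixed = TRUE))
    replicon <- if (!is.null(tus$replicon)) as.character(tus$replicon) else
      rep("all", length(sizes))
  }
  stopifnot(all(sizes >= 1))
  kind <- ifelse(sizes == 1, "single", ifelse(sizes == 2, "pair", "multi"))
  classes <- as.data.frame(table(replicon = replicon,
                                 kind = factor(kind, levels = c("single",
                                                                "pair",
                                                                "multi"))),
                           responseName = "n")
  hist <- as.data.frame(table(n_genes = sizes), responseName = "n_tus")
  hist$n_genes <- as.integer(as.character(hist$n_genes))
  multi <- sizes[sizes >= 2]
  list(classes = classes, size_histogram = hist,
       mean_genes_per_operon = if (length(multi)) mean(multi) else NA_real_,
       max_genes = max(sizes))
}

#' Genomic spans of transcription units
#'
#' @param tus `data.frame` with `tu_id` and comma-separated `gene_ids`.
#' @param ann `annotation_set` resolving the gene coordinates.
#' @return `data.frame`: tu_id, replicon, start, end, strand (strand of the
#'   first member gene), n_genes.
#' @export
tu_spans <- function(tus, ann) {
  f <- ann$features
  do.call(rbind, lapply(seq_len(nrow(tus)), function(i) {
    ids <- strsplit(as.character(tus$gene_ids[i]), ",", fixed = TRUE)[[1]]
    g <- f[match(ids, f$id), , drop = FALSE]
    if (anyNA(g$id)) stop("TU ", tus$tu_id[i], " references unknown gene(s)")
    data.frame(tu_id = tus$tu_id[i], replicon = g$replicon[1],
               start = min(g$start), end = max(g$end), strand = g$strand[1],
               n_genes = length(ids), stringsAsFactors = FALSE)
  }))
}

#' Map sRNAs into transcription units and biosynthetic gene clusters
#'
#' An sRNA belongs to a TU when its interval lies entirely within the TU's
#' genomic span on the same replicon (any strand; the strand relation is
#' recorded as `sense` or `antisense-to-TU`). It belongs to a BGC when it
#' overlaps the BGC interval by at least one nucleotide.
#'
#' @param srnas `data.frame` with id, replicon, start, end, strand.
#' @param tu_span output of [tu_spans()] (or a compatible `data.frame`).
#' @param bgc optional `data.frame` of BGC intervals (name, replicon, start,
#'   end), BED-like but 1-based inclusive.
#' @return a `data.frame` with one row per sRNA: tu membership (or `NA`),
#'   strand relation, bgc membership (or `NA`), relative position within the
#'   BGC.
#' @export
map_srnas_to_tus_bgc <- function(srnas, tu_span, bgc = NULL) {
  known <- unique(c(tu_span$replicon, if (!is.null(bgc)) bgc$replicon))
  skip <- !srnas$replicon %in% known
  if (any(skip))
    warning("sRNA(s) on unknown replicon skipped: ",
            paste(srnas$id[skip], collapse = ", "))
  srnas <- srnas[!skip, , drop = FALSE]
  gs <- GenomicRanges::GRanges(srnas$replicon,
                               IRanges::IRanges(srnas$start, srnas$end))
  gt <- GenomicRanges::GRanges(tu_span$replicon,
                               IRanges::IRanges(tu_span$start, tu_span$end))
  hits_tu <- GenomicRanges::findOverlaps(gs, gt, type = "within")
  tu_of <- rep(NA_character_, nrow(srnas))
  rel <- rep(NA_character_, nrow(srnas))
  qh <- S4Vectors::queryHits(hits_tu)
  sh <- S4Vectors::subjectHits(hits_tu)
  first <- !duplicated(qh)
  tu_of[qh[first]] <- tu_span$tu_id[sh[first]]
  rel[qh[first]] <- ifelse(srnas$strand[qh[first]] ==
                             tu_span$strand[sh[first]],
                           "sense", "antisense-to-TU")
  bgc_of <- rep(NA_character_, nrow(srnas))
  bgc_pos <- rep(NA_real_, nrow(srnas))
  if (!is.null(bgc) && nrow(bgc)) {
    gb <- GenomicRanges::GRanges(bgc$replicon,
                                 IRanges::IRanges(bgc$start, bgc$end))
    hits_b <- GenomicRanges::findOverlaps(gs, gb, minoverlap = 1L)
    qb <- S4Vectors::queryHits(hits_b)
    sb <- S4Vectors::subjectHits(hits_b)
    firstb <- !duplicated(qb)
    bgc_of[qb[firstb]] <- bgc$name[sb[firstb]]
    bgc_pos[qb[firstb]] <- (srnas$start[qb[firstb]] - bgc$start[sb[firstb]]) /
      pmax(1, bgc$end[sb[firstb]] - bgc$start[sb[firstb]])
  }
  data.frame(id = srnas$id, tu_id = tu_of, strand_relation = rel,
             bgc = bgc_of, bgc_relative_position = bgc_pos,
             stringsAsFactors = FALSE)
}
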