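#' Best local alignment of two nucleotide sequences
#'
#' Optimal Smith-Waterman local alignment with affine gaps
#' (via [Biostrings::pairwiseAlignment]); the expectation value follows the
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * score)` with
#' configurable `(K, lambda)`. Coverage is reported relative to both the
#' query (`query_coverage`, the BLAST `qcovs` convention) and the subject.
#'
#' @param q,s nucleotide sequences (character).
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   positive).
#' @param K,lambda Karlin-Altschul constants for the e-value.
#' @return one-row `data.frame`: score, evalue, query_coverage,
#'   subject_coverage, identity.
#' @export
local_align <- function(q, s, match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2, K = 0.71, lambda = 1.28) {
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  h <- align_query(q, stats::setNames(s, "s"), match, mismatch, gap_open,
                   gap_extend, K, lambda)
  h[, c("score", "evalue", "query_coverage", "subject_coverage", "identity")]
}

# one query against a named set of subjects, vectorised on the subject side
align_query <- function(q, subjects, match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2, K = 0.71, lambda = 1.28) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subjects),
    subject = Biostrings::DNAString(q),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- Biostrings::score(pa)
  qw <- IRanges::width(Biostrings::subject(pa))   # aligned span within q
  sw <- IRanges::width(Biostrings::pattern(pa))   # aligned span within subject
  m <- nchar(q)
  n <- nchar(subjects)
  data.frame(
    subject = names(subjects),
    score = score,
    evalue = K * m * n * exp(-lambda * score),
    query_coverage = qw / m,
    subject_coverage = sw / n,
    identity = Biostrings::pid(pa, type = "PID2") / 100,
    stringsAsFactors = FALSE
  )
}

# unique k-mers of a sequence (exact seeding filter)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# candidate (query, subject, strand) pairs sharing at least one exact k-mer
kmer_candidates <- function(queries, subjects, k = 11L) {
  kq <- lapply(queries, seq_kmers, k = k)
  qdf <- data.frame(kmer = unlist(kq, use.names = FALSE),
                    query = rep(names(queries), lengths(kq)),
                    stringsAsFactors = FALSE)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") subjects else
      stats::setNames(revcomp(subjects), names(subjects))
    ks <- lapply(ss, seq_kmers, k = k)
    sdf <- data.frame(kmer = unlist(ks, use.names = FALSE),
                      subject = rep(names(ss), lengths(ks)),
                      stringsAsFactors = FALSE)
    mg <- merge(qdf, sdf, by = "kmer")
    if (nrow(mg))
      out[[strand]] <- unique(data.frame(query = mg$query,
                                         subject = mg$subject,
                                         strand = strand,
                                         stringsAsFactors = FALSE))
  }
  if (!length(out))
    return(data.frame(query = character(), subject = character(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reciprocal-best-hit pairs between reference IGRs and comparator IGRs
#'
#' For each comparator genome, candidate pairs sharing an exact `k`-mer (on
#' either strand) are aligned locally; a pair `(a, b)` is reported when `b` is
#' `a`'s best-scoring hit in that genome, `a` is `b`'s best hit back, and the
#' alignment passes `evalue < evalue_max` with coverage above `min_coverage`
#' on both the query and the subject side. Score ties are broken towards the
#' lexicographically smallest id.
#'
#' @param ref_igrs named character vector of reference IGR sequences (or an
#'   `igr_set`).
#' @param other_igrs named list of per-genome named sequence vectors (or
#'   `igr_set`s).
#' @param k seed k-mer length for the candidate filter.
#' @param evalue_max,min_coverage thresholds (defaults 1e-5 and 0.7).
#' @param ... scoring parameters passed to the aligner.
#' @return named list (one element per genome) of `data.frame`s with columns
#'   query, subject, strand, score, evalue, query_coverage,
#'   subject_coverage, identity.
#' @export
find_rbbh_pairs <- function(ref_igrs, other_igrs, k = 11L, evalue_max = 1e-5,
                            min_coverage = 0.7, ...) {
  ref_igrs <- as_seq_vector(ref_igrs)
  other_igrs <- lapply(other_igrs, as_seq_vector)
  stopifnot(length(ref_igrs) > 0, length(other_igrs) > 0)
  lapply(other_igrs, function(subjects) {
    cand <- kmer_candidates(ref_igrs, subjects, k = k)
    if (!nrow(cand)) return(empty_hits())
    hits <- do.call(rbind, lapply(split(cand, cand$query), function(cc) {
      q <- cc$query[1]
      ss <- subjects[cc$subject]
      ss[cc$strand == "-"] <- revcomp(ss[cc$strand == "-"])
      names(ss) <- cc$subject
      h <- align_query(ref_igrs[[q]], ss, ...)
      h$strand <- cc$strand
      h$query <- q
      h
    }))
    rownames(hits) <- NULL
    # deterministic best hit per query and per subject (score, then id)
    hits <- hits[order(hits$query, -hits$score, hits$subject), , drop = FALSE]
    best_fwd <- hits[!duplicated(hits$query), , drop = FALSE]
    hits2 <- hits[order(hits$subject, -hits$score, hits$query), , drop = FALSE]
    best_rev <- hits2[!duplicated(hits2$subject), , drop = FALSE]
    key_rev <- paste(best_rev$query, best_rev$subject)
    keep <- paste(best_fwd$query, best_fwd$subject) %in% key_rev &
      best_fwd$evalue < evalue_max &
      best_fwd$query_coverage > min_coverage &
      best_fwd$subject_coverage > min_coverage
    out <- best_fwd[keep, c("query", "subject", "strand", "score", "evalue",
                            "query_coverage", "subject_coverage", "identity"),
                    drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

as_seq_vector <- function(x) {
  if (inherits(x, "igr_set")) return(stats::setNames(x$sequence, x$id))
  if (methods::is(x, "DNAStringSet"))
    return(stats::setNames(as.character(x), names(x)))
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(), strand = character(),
             score = numeric(), evalue = numeric(), query_coverage = numeric(),
             subject_coverage = numeric(), identity = numeric(),
             stringsAsFactors = FALSE)
}

#' Call cross-strain conservation of reference IGRs
#'
#' An IGR is conserved when it has a reciprocal-best-hit partner in at least
#' `min_strains` comparator genomes. The conservation profile is the
#' histogram of the number of genomes with a homolog over the conserved IGRs;
#' IGR families are the connected components of the RBBH graph.
#'
#' @param ref_ids reference IGR ids (or an `igr_set`).
#' @param rbbh result of [find_rbbh_pairs()].
#' @param min_strains conservation threshold (default 4).
#' @return a list with `records` (igr_id, genomes_with_homolog, conserved),
#'   `profile` (genomes_with_homolog vs number of conserved IGRs) and
#'   `families` (node, family membership of the RBBH graph).
#' @export
call_conserved <- function(ref_ids, rbbh, min_strains = 4L) {
  if (inherits(ref_ids, "igr_set")) ref_ids <- ref_ids$id
  if (min_strains > length(rbbh))
    stop("min_strains (", min_strains, ") exceeds the number of comparator ",
         "genomes (", length(rbbh), ")")
  counts <- rowSums(vapply(rbbh, function(h) {
    if (is.null(h) || nrow(h) == 0) return(rep(FALSE, length(ref_ids)))
    ref_ids %in% h$query
  }, logical(length(ref_ids))))
  records <- data.frame(igr_id = ref_ids,
                        genomes_with_homolog = as.integer(counts),
                        conserved = counts >= min_strains,
                        stringsAsFactors = FALSE)
  tab <- table(factor(records$genomes_with_homolog[records$conserved],
                      levels = seq_len(length(rbbh))))
  profile <- data.frame(genomes_with_homolog = as.integer(names(tab)),
                        n_igrs = as.integer(tab))
  edges <- do.call(rbind, lapply(names(rbbh), function(g) {
    h <- rbbh[[g]]
    if (is.null(h) || nrow(h) == 0) return(NULL)
    data.frame(from = paste0("ref::", h$query),
               to = paste0(g, "::", h$subject), stringsAsFactors = FALSE)
  }))
  families <- if (is.null(edges) || !nrow(edges)) {
    data.frame(node = character(), family = integer())
  } else {
    gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
    comp <- igraph::components(gr)
    data.frame(node = names(comp$membership),
               family = as.integer(comp$membership),
               stringsAsFactors = FALSE)
  }
  list(records = records, profile = profile, families = families)
}
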