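#' Read a (multi-replicon) genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by the first whitespace-separated
#'   token of each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("`genome` must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}

feature_kinds <- c("CDS", "tRNA", "rRNA", "putative_sRNA", "antisense", "other")

#' Read genome features from a GFF3 file
#'
#' Feature types outside `CDS`/`tRNA`/`rRNA`/`putative_sRNA`/`antisense`
#' are mapped to kind `other` (the original type is kept in `source` context
#' via the GFF source column).
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` of features (id, replicon, start, end, strand,
#'   kind, source).
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  id <- md$ID
  if (is.null(id)) id <- md$Name
  if (is.null(id) || anyNA(id)) {
    fallback <- paste0("f", seq_along(gr))
    id <- if (is.null(id)) fallback else ifelse(is.na(id), fallback, id)
  }
  kind <- as.character(md$type)
  kind[!kind %in% feature_kinds] <- "other"
  src <- as.character(md$source %||% rep("unknown", length(gr)))
  data.frame(
    id = as.character(id),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    source = src,
    stringsAsFactors = FALSE
  )
}

#' Write an annotation set to GFF3
#'
#' @param ann an `annotation_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(ann, path) {
  f <- ann$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$replicon,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand
  )
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$source <- f$source
  S4Vectors::mcols(gr)$phase <- ifelse(f$kind == "CDS", 0L, NA_integer_)
  GenomeInfoDb::seqlengths(gr) <- ann$replicons[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load and validate a genome plus its feature annotation
#'
#' Features are checked against the replicon universe (existence, coordinate
#' bounds, strand, unique ids) and returned sorted by (replicon, start).
#'
#' @param genome a `DNAStringSet`, named character vector of sequences, or a
#'   FASTA path.
#' @param features a feature `data.frame` (columns id, replicon, start, end,
#'   strand, kind and optionally source) or a GFF3 path.
#' @return an object of class `annotation_set`: a list with elements
#'   `replicons` (named integer vector of lengths) and `features`
#'   (validated, sorted `data.frame`).
#' @export
load_annotation_set <- function(genome, features) {
  genome <- as_genome(genome)
  if (is.character(features) && length(features) == 1)
    features <- read_features_gff3(features)
  stopifnot(is.data.frame(features))
  need <- c("id", "replicon", "start", "end", "strand", "kind")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(features$source))
    features$source <- rep("unknown", nrow(features))
  features <- features[, c(need, "source")]
  features$id <- as.character(features$id)
  features$replicon <- as.character(features$replicon)
  features$strand <- as.character(features$strand)
  features$kind <- as.character(features$kind)

  replicons <- stats::setNames(Biostrings::width(genome), names(genome))
  if (nrow(features)) {
    bad <- !features$replicon %in% names(replicons)
    if (any(bad))
      stop("feature(s) on unknown replicon: ",
           paste(features$id[bad], collapse = ", "))
    bad <- !(features$start >= 1 & features$start <= features$end &
               features$end <= replicons[features$replicon])
    if (any(bad))
      stop("feature(s) with malformed coordinates: ",
           paste(features$id[bad], collapse = ", "))
    if (!all(features$strand %in% c("+", "-")))
      stop("feature(s) with undefined strand: ",
           paste(features$id[!features$strand %in% c("+", "-")],
                 collapse = ", "))
    if (anyDuplicated(features$id))
      stop("duplicate feature id(s): ",
           paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
    features <- features[order(features$replicon, features$start,
                               features$end, features$id), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(genome = genome, replicons = replicons, features = features),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$replicons), "replicon(s),",
      nrow(x$features), "feature(s)\n")
  invisible(x)
}

#' Merge two annotation sets into one coherent set
#'
#' Same-strand features on the same replicon that overlap by at least
#' `min_overlap` nucleotides are collapsed into one record spanning their
#' union, recording all contributing sources. Features with conflicting
#' strands are kept separate. The overlap report counts features of `set_b`
#' overlapping any feature of `set_a` (same strand).
#'
#' @param set_a,set_b `annotation_set` objects over the same replicons.
#' @param min_overlap minimum overlap (nt) to collapse; default 1.
#' @return a list with `merged` (an `annotation_set`), `overlap_count`
#'   (number of `set_b` features overlapping `set_a`), and `report`
#'   (per-feature `data.frame` for `set_b`).
#' @export
merge_annotations <- function(set_a, set_b, min_overlap = 1L) {
  stopifnot(inherits(set_a, "annotation_set"), inherits(set_b, "annotation_set"))
  if (!setequal(names(set_a$replicons), names(set_b$replicons)))
    stop("annotation sets cover different replicon universes")
  fa <- set_a$features
  fb <- set_b$features
  all_f <- rbind(fa, fb)
  gr <- GenomicRanges::GRanges(all_f$replicon,
                               IRanges::IRanges(all_f$start, all_f$end),
                               strand = all_f$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L - min_overlap,
                               with.revmap = TRUE, ignore.strand = FALSE)
  revmap <- S4Vectors::mcols(red)$revmap
  merged <- do.call(rbind, lapply(seq_along(red), function(i) {
    idx <- revmap[[i]]
    ids <- unique(all_f$id[idx])
    kinds <- unique(all_f$kind[idx])
    data.frame(
      id = if (length(ids) == 1) ids else
        paste0("m_", paste(ids, collapse = "_")),
      replicon = as.character(GenomicRanges::seqnames(red))[i],
      start = GenomicRanges::start(red)[i],
      end = GenomicRanges::end(red)[i],
      strand = as.character(GenomicRanges::strand(red))[i],
      kind = if (length(kinds) == 1) kinds else "other",
      source = paste(unique(all_f$source[idx]), collapse = "+"),
      stringsAsFactors = FALSE
    )
  }))
  ga <- GenomicRanges::GRanges(fa$replicon, IRanges::IRanges(fa$start, fa$end),
                               strand = fa$strand)
  gb <- GenomicRanges::GRanges(fb$replicon, IRanges::IRanges(fb$start, fb$end),
                               strand = fb$strand)
  hits <- GenomicRanges::countOverlaps(gb, ga, minoverlap = min_overlap,
                                       ignore.strand = FALSE)
  report <- data.frame(id = fb$id, overlaps_a = hits > 0,
                       stringsAsFactors = FALSE)
  merged_set <- load_annotation_set(set_a$genome, merged)
  list(merged = merged_set, overlap_count = sum(hits > 0), report = report)
}
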