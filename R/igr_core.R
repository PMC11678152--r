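#' Classify an intergenic region by the orientation of its flanking genes
#'
#' The four classes describe the strands of the left and right flanking gene:
#' convergent genes (`+`,`-`) enclose a double-terminator (DT) region,
#' divergent genes (`-`,`+`) a double-promoter (DP) region, and co-oriented
#' genes give CO_F (`+`,`+`) or CO_R (`-`,`-`).
#'
#' @param left_strand,right_strand character vectors over `{"+", "-"}`.
#' @return character vector over `{"DP", "DT", "CO_F", "CO_R"}`.
#' @export
classify_orientation <- function(left_strand, right_strand) {
  stopifnot(all(left_strand %in% c("+", "-")),
            all(right_strand %in% c("+", "-")))
  out <- ifelse(left_strand == "+",
                ifelse(right_strand == "-", "DT", "CO_F"),
                ifelse(right_strand == "+", "DP", "CO_R"))
  out
}

#' GC content of nucleotide sequences
#'
#' `N` (and any other ambiguity code) is excluded from the denominator; an
#' all-ambiguous sequence yields `NA`.
#'
#' @param seq character vector of sequences over `{A,C,G,T,U,N}`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(
    chartr("Uu", "Tt", seq)))
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(acgt)
  out <- (acgt[, "G"] + acgt[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Extract intergenic regions (IGRs) from an annotation set
#'
#' An IGR is any gap of at least one nucleotide between consecutive
#' delimiting features (by default CDS, tRNA and rRNA) on a replicon.
#' Overlapping or abutting genes yield no IGR; a gene nested inside another
#' does not reset the right boundary (a running maximum of feature ends is
#' used). Terminal regions before the first and after the last gene have only
#' one flanking gene and are excluded unless `include_terminal = TRUE` (their
#' orientation class is then `NA`). Sequences are reported on the forward
#' strand and are not trimmed.
#'
#' @param ann an `annotation_set`.
#' @param delimiters feature kinds that delimit IGRs.
#' @param include_terminal include the regions flanking the first/last gene.
#' @param min_length minimum IGR length (nt), default 1.
#' @return a `data.frame` (class `igr_set`) with columns id, replicon, start,
#'   end, length, left_gene, right_gene, left_strand, right_strand,
#'   orientation_class, sequence, gc.
#' @export
extract_igrs <- function(ann, delimiters = c("CDS", "tRNA", "rRNA"),
                         include_terminal = FALSE, min_length = 1L) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- list()
  for (rep_name in names(ann$replicons)) {
    f <- ann$features[ann$features$replicon == rep_name &
                        ann$features$kind %in% delimiters, , drop = FALSE]
    rlen <- ann$replicons[[rep_name]]
    n <- nrow(f)
    if (n == 0) next
    if (include_terminal && f$start[1] > 1) {
      rows[[length(rows) + 1]] <- data.frame(
        replicon = rep_name, start = 1L, end = f$start[1] - 1L,
        left_gene = NA_character_, right_gene = f$id[1],
        left_strand = NA_character_, right_strand = f$strand[1],
        stringsAsFactors = FALSE)
    }
    if (n >= 2) {
      run_end <- f$end[1]
      run_idx <- 1L
      for (i in 2:n) {
        gap_start <- run_end + 1L
        gap_end <- f$start[i] - 1L
        if (gap_end - gap_start + 1L >= min_length) {
          rows[[length(rows) + 1]] <- data.frame(
            replicon = rep_name, start = gap_start, end = gap_end,
            left_gene = f$id[run_idx], right_gene = f$id[i],
            left_strand = f$strand[run_idx], right_strand = f$strand[i],
            stringsAsFactors = FALSE)
        }
        if (f$end[i] > run_end) {
          run_end <- f$end[i]
          run_idx <- i
        }
      }
    }
    last_end <- max(f$end)
    if (include_terminal && last_end < rlen) {
      i <- which.max(f$end)
      rows[[length(rows) + 1]] <- data.frame(
        replicon = rep_name, start = last_end + 1L, end = rlen,
        left_gene = f$id[i], right_gene = NA_character_,
        left_strand = f$strand[i], right_strand = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(id = character(), replicon = character(),
                      start = integer(), end = integer(), length = integer(),
                      left_gene = character(), right_gene = character(),
                      left_strand = character(), right_strand = character(),
                      orientation_class = character(), sequence = character(),
                      gc = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("igr_set", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start + 1L
  out$orientation_class <- NA_character_
  both <- !is.na(out$left_strand) & !is.na(out$right_strand)
  out$orientation_class[both] <-
    classify_orientation(out$left_strand[both], out$right_strand[both])
  out$sequence <- vapply(seq_len(nrow(out)), function(i) {
    as.character(Biostrings::subseq(ann$genome[[out$replicon[i]]],
                                    out$start[i], out$end[i]))
  }, character(1))
  out$gc <- gc_content(out$sequence)
  out$id <- paste0("igr_", out$replicon, "_",
                   stats::ave(seq_len(nrow(out)), out$replicon,
                              FUN = seq_along))
  out <- out[, c("id", "replicon", "start", "end", "length", "left_gene",
                 "right_gene", "left_strand", "right_strand",
                 "orientation_class", "sequence", "gc")]
  rownames(out) <- NULL
  class(out) <- c("igr_set", "data.frame")
  out
}

# longest ORF (in residues, excluding initiator and stop codons) over six
# frames; start codons ATG/GTG, stops TAA/TAG/TGA
longest_orf_aa <- function(seq, starts = c("ATG", "GTG"),
                           stops = c("TAA", "TAG", "TGA")) {
  best <- 0L
  for (s in c(toupper(seq), revcomp(toupper(seq)))) {
    n <- nchar(s)
    for (frame in 0:2) {
      if (n - frame < 3) next
      ncod <- (n - frame) %/% 3
      cods <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                        frame + 3L * seq_len(ncod))
      open <- NA_integer_
      for (i in seq_along(cods)) {
        if (cods[i] %in% stops) {
          if (!is.na(open)) best <- max(best, i - open - 1L)
          open <- NA_integer_
        } else if (is.na(open) && cods[i] %in% starts) {
          open <- i
        }
      }
    }
  }
  best
}

#' Coding-potential call for intergenic regions
#'
#' A simple longest-open-reading-frame screen: ORFs start at ATG or GTG
#' (GTG initiation is common in actinobacteria), end at TAA/TAG/TGA, and are
#' searched in all six frames. The length is reported in residues, excluding
#' the initiator and stop codons. A region is flagged coding when the longest
#' ORF reaches `min_aa` residues.
#'
#' @param igrs an `igr_set` or a character vector of sequences (optionally
#'   named).
#' @param min_aa residue threshold for the coding flag (default 100).
#' @return a `data.frame` with igr_id, longest_orf_aa, is_coding.
#' @export
coding_call <- function(igrs, min_aa = 100L) {
  if (inherits(igrs, "igr_set")) {
    ids <- igrs$id
    seqs <- igrs$sequence
  } else {
    seqs <- as.character(igrs)
    ids <- names(igrs) %||% paste0("seq", seq_along(seqs))
  }
  aa <- vapply(seqs, longest_orf_aa, integer(1), USE.NAMES = FALSE)
  data.frame(igr_id = ids, longest_orf_aa = aa, is_coding = aa >= min_aa,
             stringsAsFactors = FALSE)
}

#' Write an IGR table and/or FASTA
#'
#' @param igrs an `igr_set`.
#' @param tsv,fasta output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_igrs <- function(igrs, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    cols <- setdiff(names(igrs), "sequence")
    utils::write.table(igrs[, cols], tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(igrs$sequence, igrs$id))
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(c(tsv = tsv, fasta = fasta))
}
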