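#' Default base-pair energies for the simplified folding model
#'
#' Nested-structure folding uses a base-pair energy model (GC = -3, AU = -2,
#' GU = -1 kcal/mol) with a minimum hairpin loop of 3 unpaired bases, rather
#' than a full nearest-neighbour loop model. This is sufficient to rank
#' windows by thermodynamic stability relative to shuffled backgrounds.
#' @export
pair_energies <- function() c(gc = -3, au = -2, gu = -1)

#' Minimum-free-energy nested secondary structure
#'
#' Dynamic-programming optimum over nested structures under the base-pair
#' energy model of [pair_energies()], with hairpin loops of at least
#' `min_loop` unpaired bases. The empty structure (energy 0) is always
#' admissible, so the optimum is never positive.
#'
#' @param seq a nucleotide sequence (`T` and `U` are equivalent).
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3).
#' @param energies named vector as returned by [pair_energies()].
#' @param model `"pair"` (default) scores every base pair; `"stack"` scores
#'   a pair only when it is directly enclosed by another pair, so a helix of
#'   `L` pairs contributes `L - 1` pair energies and isolated pairs score 0.
#'   The stacked model rewards contiguous helices and is the one used by the
#'   comparative screen.
#' @return a list with `mfe` (kcal/mol, `<= 0`) and `pairs` (two-column
#'   matrix of 1-based paired positions).
#' @export
fold_mfe <- function(seq, min_loop = 3L, energies = pair_energies(),
                     model = c("pair", "stack")) {
  stopifnot(nchar(seq) >= 1)
  model <- match.arg(model)
  fn <- if (model == "pair") .fold_mfe_cpp else .fold_stack_cpp
  res <- fn(seq_to_codes(seq), energies[["gc"]], energies[["au"]],
            energies[["gu"]], as.integer(min_loop))
  res$mfe <- as.numeric(res$mfe)
  res
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffling: every shuffle has exactly the
#' same 16-entry dinucleotide count vector (and hence mononucleotide
#' composition and terminal bases) as the input. `method = "mono"` falls
#' back to a plain permutation of the letters.
#'
#' @param seq a sequence (character scalar).
#' @param n number of shuffles.
#' @param method `"dinucleotide"` (default) or `"mono"`.
#' @return character vector of `n` shuffled sequences.
#' @export
dinuc_shuffle <- function(seq, n = 1L, method = c("dinucleotide", "mono")) {
  method <- match.arg(method)
  x <- seq_chars(toupper(seq))
  L <- length(x)
  if (method == "mono")
    return(vapply(seq_len(n), function(i) collapse_chars(sample(x)),
                  character(1)))
  if (L < 3 || length(unique(x)) < 2)
    return(rep(collapse_chars(x), n))
  from <- x[-L]
  to <- x[-1]
  last <- x[L]
  verts <- unique(x)
  out_edges <- split(to, factor(from, levels = verts))
  vapply(seq_len(n), function(i) {
    # choose, for every vertex with out-edges except the terminal one, a
    # "last" out-edge such that the last-edge graph reaches the terminal
    # vertex from everywhere (Altschul-Erickson connectivity condition)
    repeat {
      last_edge <- vapply(verts, function(v) {
        e <- out_edges[[v]]
        if (v == last || length(e) == 0) NA_character_
        else e[sample.int(length(e), 1)]
      }, character(1))
      ok <- TRUE
      for (v in verts) {
        if (v == last || is.na(last_edge[[v]])) next
        seen <- character(0)
        cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute remaining out-edges; append the reserved last edge
    lists <- lapply(verts, function(v) {
      e <- out_edges[[v]]
      if (length(e) == 0) return(character(0))
      if (v == last && is.na(last_edge[[v]])) return(sample(e))
      reserved <- last_edge[[v]]
      if (is.na(reserved)) return(sample(e))
      idx <- which(e == reserved)[1]
      rest <- e[-idx]
      c(if (length(rest)) sample(rest) else character(0), reserved)
    })
    names(lists) <- verts
    ptr <- stats::setNames(integer(length(verts)), verts)
    res <- character(L)
    res[1] <- x[1]
    cur <- x[1]
    for (j in 2:L) {
      ptr[[cur]] <- ptr[[cur]] + 1L
      nxt <- lists[[cur]][ptr[[cur]]]
      res[j] <- nxt
      cur <- nxt
    }
    collapse_chars(res)
  }, character(1))
}

#' Thermodynamic stability z-score of a sequence
#'
#' `z = (mfe(seq) - mean(mfe(shuffles))) / sd(mfe(shuffles))` against
#' dinucleotide-preserving shuffles. Strongly negative z indicates a
#' structure more stable than expected from composition alone.
#'
#' @param seq sequence (length >= 20 recommended).
#' @param n_shuffles number of shuffles (>= 30 recommended).
#' @param seed optional RNG seed (local to this call).
#' @param method shuffle type, see [dinuc_shuffle()].
#' @inheritParams fold_mfe
#' @return list with `z`, `mfe`, `null_mean`, `null_sd`.
#' @export
structure_z_score <- function(seq, n_shuffles = 30L, seed = NULL,
                              method = "dinucleotide", min_loop = 3L,
                              energies = pair_energies(), model = "stack") {
  mfe <- fold_mfe(seq, min_loop, energies, model)$mfe
  null <- with_seed(seed, {
    sh <- dinuc_shuffle(seq, n_shuffles, method)
    vapply(sh, function(s) fold_mfe(s, min_loop, energies, model)$mfe,
           numeric(1))
  })
  s <- stats::sd(null)
  if (is.na(s) || s == 0) {
    warning("degenerate shuffle distribution (sd = 0); z set to 0")
    z <- 0
  } else z <- (mfe - mean(null)) / s
  list(z = z, mfe = mfe, null_mean = mean(null), null_sd = s)
}

align_rows_matrix <- function(rows) {
  stopifnot(length(rows) >= 2, length(unique(nchar(rows))) == 1)
  m <- do.call(rbind, lapply(toupper(rows), seq_chars))
  rownames(m) <- names(rows)
  # drop all-gap columns
  m[, colSums(m != "-") > 0, drop = FALSE]
}

#' Structure conservation index of an alignment
#'
#' The consensus fold scores a column pair only when at least
#' `min_pair_frac` of the rows can form a base pair there (gapped rows
#' cannot); the pair energy is then the mean over all rows (non-pairing rows
#' contributing 0). The SCI is the consensus minimum energy divided by the
#' mean minimum energy of the ungapped individual sequences; identical rows
#' give exactly 1, unrelated rows drive it towards 0, and compensatory
#' (pair-preserving) substitutions keep it high.
#'
#' @param rows character vector (>= 2) of equal-length gapped sequences.
#' @param min_pair_frac minimum fraction of pairable rows per column pair.
#' @param cov_weight covariance bonus (kcal/mol), granted at fully
#'   consistent columns only, per distinct pair type differing from the
#'   majority type at both positions; compensatory substitutions therefore
#'   push the SCI above 1.
#' @param nopair_penalty penalty (kcal/mol) per non-pairing row at a
#'   consensus column pair, so chance pairing among diverged rows cannot
#'   assemble a consensus structure.
#' @inheritParams fold_mfe
#' @return list with `sci`, `consensus_mfe`, `mean_individual_mfe`.
#' @export
consensus_sci <- function(rows, min_pair_frac = 0.7, min_loop = 3L,
                          energies = pair_energies(), model = "stack",
                          cov_weight = 6, nopair_penalty = 10) {
  m <- align_rows_matrix(rows)
  n <- ncol(m)
  cons <- if (n == 0) 0 else {
    codes <- matrix(-1L, nrow(m), n)
    idx <- match(m, c("A", "C", "G", "T", "U"))
    idx[idx == 5L] <- 4L
    codes[] <- ifelse(is.na(idx), -1L, idx - 1L)
    E <- .consensus_energy_cpp(codes, min_pair_frac, energies[["gc"]],
                               energies[["au"]], energies[["gu"]],
                               as.integer(min_loop), cov_weight,
                               nopair_penalty)
    fn <- if (model == "pair") .fold_matrix_cpp else .fold_stack_matrix_cpp
    as.numeric(fn(E, as.integer(min_loop))$mfe)
  }
  indiv <- vapply(seq_len(nrow(m)), function(r) {
    s <- collapse_chars(m[r, m[r, ] != "-"])
    if (nchar(s) == 0) 0 else fold_mfe(s, min_loop, energies, model)$mfe
  }, numeric(1))
  denom <- mean(indiv)
  sci <- if (denom == 0) 0 else cons / denom
  list(sci = sci, consensus_mfe = cons, mean_individual_mfe = denom)
}

#' Default logistic coefficients of the structured-RNA classifier
#'
#' The probability that a window holds a conserved, thermodynamically stable
#' structure is `plogis(a * (-z) + b * sci + c)`, combining the stability
#' z-score and the structure conservation index, with the decision taken at
#' probability 0.5. The coefficients were calibrated once on the bundled
#' synthetic strain-family generator (together with the covariance weight of
#' [consensus_sci()]) and are recorded here as package configuration.
#' @export
structure_classifier_coefs <- function() c(a = 0.5, b = 12.0, c = -12.2)

score_alignment_window <- function(m, n_shuffles, min_pair_frac, min_loop,
                                   energies, coefs, model = "stack",
                                   cov_weight = 6, nopair_penalty = 10) {
  rows <- apply(m, 1, collapse_chars)
  ref_seq <- collapse_chars(m[1, m[1, ] != "-"])
  if (nchar(ref_seq) < 20) return(NULL)
  sci <- consensus_sci(rows, min_pair_frac, min_loop, energies, model,
                       cov_weight, nopair_penalty)$sci
  zres <- structure_z_score(ref_seq, n_shuffles, seed = NULL,
                            min_loop = min_loop, energies = energies,
                            model = model)
  p <- stats::plogis(coefs[["a"]] * (-zres$z) + coefs[["b"]] * sci +
                       coefs[["c"]])
  list(p = p, z = zres$z, sci = sci, mfe = zres$mfe)
}

mean_pairwise_identity <- function(m) {
  nr <- nrow(m)
  if (nr < 2) return(1)
  tot <- 0
  cnt <- 0
  for (i in 1:(nr - 1)) for (j in (i + 1):nr) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(keep)) next
    tot <- tot + mean(m[i, keep] == m[j, keep])
    cnt <- cnt + 1
  }
  if (cnt == 0) 1 else tot / cnt
}

#' Windowed comparative structure screen of a conserved IGR alignment
#'
#' The alignment (reference strain in the first row) is cut into windows of
#' at most `window_max` columns advancing by `step`; rows are dropped
#' (never the reference) until the mean pairwise identity reaches
#' `opt_id` percent or only two rows remain. Each window is scored on both
#' strands with the logistic classifier over (z-score, SCI); the strand with
#' the higher probability is reported. Positive windows (probability above
#' `p_threshold`) on the same strand that overlap in reference coordinates
#' are merged into a single call, so one IGR can yield several distinct
#' calls.
#'
#' @param alignment named character vector of equal-length gapped sequences;
#'   the first element is the reference row.
#' @param igr_id id copied into the output.
#' @param window_max,step window size and step in alignment columns.
#' @param opt_id target mean pairwise identity (percent) for row filtering.
#' @param p_threshold decision threshold on the structured-class probability.
#' @param n_shuffles shuffles for the z-score.
#' @param seed optional RNG seed (local to this call).
#' @param coefs logistic coefficients, see [structure_classifier_coefs()].
#' @param min_pair_frac,cov_weight,nopair_penalty consensus-fold
#'   parameters, see [consensus_sci()].
#' @inheritParams fold_mfe
#' @return `data.frame` of structure calls: igr_id, window_start, window_end
#'   (reference coordinates within the IGR), strand, mfe, z, sci,
#'   p_structured, positive; merged positive calls plus (attribute
#'   `"windows"`) the per-window scores.
#' @export
scan_igr_windows <- function(alignment, igr_id = "igr", window_max = 200L,
                             step = 100L, opt_id = 70, p_threshold = 0.5,
                             n_shuffles = 30L, seed = NULL,
                             coefs = structure_classifier_coefs(),
                             min_pair_frac = 0.7, min_loop = 3L,
                             energies = pair_energies(), model = "stack",
                             cov_weight = 6, nopair_penalty = 10) {
  m <- align_rows_matrix(alignment)
  L <- ncol(m)
  with_seed(seed, {
    starts <- if (L <= window_max) 1L else {
      st <- seq(1L, L - window_max + 1L, by = step)
      if (st[length(st)] + window_max - 1L < L)
        st <- c(st, L - window_max + 1L)
      st
    }
    refpos <- cumsum(m[1, ] != "-")  # alignment column -> reference position
    win_rows <- list()
    for (st in starts) {
      en <- min(st + window_max - 1L, L)
      w <- m[, st:en, drop = FALSE]
      # drop mostly-gapped rows (never the reference)
      frac_gap <- rowMeans(w == "-")
      keep <- frac_gap <= 0.5
      keep[1] <- TRUE
      w <- w[keep, , drop = FALSE]
      # prune rows furthest from the rest until mean identity reaches opt_id
      while (nrow(w) > 2 &&
             mean_pairwise_identity(w) < opt_id / 100) {
        ids <- vapply(2:nrow(w), function(r)
          mean_pairwise_identity(w[c(1, r), , drop = FALSE]), numeric(1))
        w <- w[-(which.min(ids) + 1L), , drop = FALSE]
      }
      if (nrow(w) < 2) next
      ref_from <- refpos[st] + (m[1, st] == "-")  # first ref base in window
      ref_to <- refpos[en]
      if (ref_to < ref_from) next
      sc_p <- score_alignment_window(w, n_shuffles, min_pair_frac, min_loop,
                                     energies, coefs, model, cov_weight,
                                     nopair_penalty)
      w_rc <- do.call(rbind, lapply(seq_len(nrow(w)), function(r)
        rev(chartr("ACGTU", "TGCAA", w[r, ]))))
      rownames(w_rc) <- rownames(w)
      sc_m <- score_alignment_window(w_rc, n_shuffles, min_pair_frac,
                                     min_loop, energies, coefs, model,
                                     cov_weight, nopair_penalty)
      if (is.null(sc_p) && is.null(sc_m)) next
      use_m <- is.null(sc_p) || (!is.null(sc_m) && sc_m$p > sc_p$p)
      sc <- if (use_m) sc_m else sc_p
      win_rows[[length(win_rows) + 1]] <- data.frame(
        igr_id = igr_id, window_start = ref_from, window_end = ref_to,
        strand = if (use_m) "-" else "+", mfe = sc$mfe, z = sc$z,
        sci = sc$sci, p_structured = unname(sc$p),
        positive = unname(sc$p) > p_threshold, stringsAsFactors = FALSE)
    }
    windows <- if (length(win_rows)) do.call(rbind, win_rows) else
      empty_structure_calls()
    calls <- merge_positive_windows(windows)
    attr(calls, "windows") <- windows
    calls
  })
}

empty_structure_calls <- function() {
  data.frame(igr_id = character(), window_start = integer(),
             window_end = integer(), strand = character(), mfe = numeric(),
             z = numeric(), sci = numeric(), p_structured = numeric(),
             positive = logical(), stringsAsFactors = FALSE)
}

merge_positive_windows <- function(windows) {
  pos <- windows[windows$positive, , drop = FALSE]
  if (!nrow(pos)) return(empty_structure_calls())
  out <- lapply(split(pos, pos$strand), function(p) {
    ir <- IRanges::IRanges(p$window_start, p$window_end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    do.call(rbind, lapply(seq_along(red), function(i) {
      idx <- revmap[[i]]
      data.frame(igr_id = p$igr_id[1],
                 window_start = IRanges::start(red)[i],
                 window_end = IRanges::end(red)[i],
                 strand = p$strand[1],
                 mfe = min(p$mfe[idx]), z = min(p$z[idx]),
                 sci = max(p$sci[idx]),
                 p_structured = max(p$p_structured[idx]),
                 positive = TRUE, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$window_start), , drop = FALSE]
}

#' Scan a sequence for intrinsic (rho-independent) terminator hairpins
#'
#' Reports every locus with a stem of at least `min_stem` base pairs
#' (Watson-Crick or GU wobble), a loop of 3-10 nt, and at least `min_u`
#' thymines within the `tail_window` nt downstream of the stem (the U-tail).
#' The score is `stem_len + u_tail_len - loop_len / 2`. Overlapping
#' candidate hairpins are reduced to the best-scoring one per locus.
#'
#' @param seq sequence to scan (length >= 20).
#' @param strand `"+"` scans the sequence as given; `"-"` scans its reverse
#'   complement (positions then refer to the reverse-complemented sequence).
#' @param min_stem,max_stem stem length bounds (bp).
#' @param loop_range allowed loop lengths (nt).
#' @param tail_window,min_u downstream window (nt) and minimum T count.
#' @return `data.frame`: position (1-based start of the stem), strand,
#'   stem_len, loop_len, u_tail_len, score.
#' @export
detect_terminators <- function(seq, strand = "+", min_stem = 4L,
                               max_stem = 12L, loop_range = c(3L, 10L),
                               tail_window = 8L, min_u = 3L) {
  stopifnot(nchar(seq) >= 20)
  s <- toupper(chartr("U", "T", seq))
  if (strand == "-") s <- revcomp(s)
  x <- seq_chars(s)
  n <- length(x)
  can_pair <- function(a, b) {
    ab <- paste0(a, b)
    ab %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  hits <- list()
  for (i in seq_len(n)) {
    for (stem in min_stem:max_stem) {
      for (loop in loop_range[1]:loop_range[2]) {
        j_end <- i + 2L * stem + loop - 1L
        if (j_end + 1L > n) next
        s1 <- x[i:(i + stem - 1L)]
        s2 <- x[(i + stem + loop):j_end]
        if (!all(can_pair(s1, rev(s2)))) next
        tail_end <- min(n, j_end + tail_window)
        u_tail <- sum(x[(j_end + 1L):tail_end] == "T")
        if (u_tail < min_u) next
        hits[[length(hits) + 1]] <- data.frame(
          position = i, strand = strand, stem_len = stem, loop_len = loop,
          u_tail_len = u_tail, score = stem + u_tail - loop / 2,
          end = j_end, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(position = integer(), strand = character(),
                      stem_len = integer(), loop_len = integer(),
                      u_tail_len = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$position), , drop = FALSE]
  kept <- logical(nrow(h))
  occupied <- rep(FALSE, n)
  for (r in seq_len(nrow(h))) {
    span <- h$position[r]:h$end[r]
    if (!any(occupied[span])) {
      kept[r] <- TRUE
      occupied[span] <- TRUE
    }
  }
  h <- h[kept, setdiff(names(h), "end"), drop = FALSE]
  h <- h[order(h$position), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Screen performance record
#'
#' Encodes the randomization-based estimate: specificity is
#' `1 - n_false_positive / n_random` and sensitivity is
#' `n_known_detected / n_known` (missing when no known set is given).
#'
#' @param n_false_positive,n_random,n_known_detected,n_known counts.
#' @return list of class `screen_performance`.
#' @export
screen_performance <- function(n_false_positive, n_random,
                               n_known_detected = NA_integer_,
                               n_known = NA_integer_) {
  structure(list(
    specificity = 1 - n_false_positive / n_random,
    sensitivity = if (!is.na(n_known) && n_known > 0)
      n_known_detected / n_known else NA_real_,
    n_random = n_random, n_false_positive = n_false_positive,
    n_known = n_known, n_known_detected = n_known_detected
  ), class = "screen_performance")
}

#' @export
print.screen_performance <- function(x, ...) {
  cat(sprintf("screen performance: specificity %.4f (%d FP / %d random)",
              x$specificity, x$n_false_positive, x$n_random))
  if (!is.na(x$sensitivity))
    cat(sprintf(", sensitivity %.4f (%d / %d known)",
                x$sensitivity, x$n_known_detected, x$n_known))
  cat("\n")
  invisible(x)
}

#' Randomization estimate of screen specificity and sensitivity
#'
#' Specificity: the full windowed screen is re-run `n_iter` times on
#' composition-matched randomizations of the real IGR family alignments
#' (columns of one family alignment are permuted jointly, preserving per-row
#' composition and column-wise conservation while destroying helices); a
#' false positive is a replicate yielding any positive call. Sensitivity:
#' the fraction of families in `known_ids` recovered by the screen on the
#' real alignments.
#'
#' @param families named list of family alignments (each as accepted by
#'   [scan_igr_windows()]); names are IGR ids.
#' @param known_ids ids of families holding known ncRNAs (may be empty:
#'   sensitivity is then `NA`).
#' @param n_iter number of randomized replicates (warning below 100).
#' @param seed RNG seed (local to this call).
#' @param ... screen parameters passed to [scan_igr_windows()].
#' @return a [screen_performance()] object.
#' @export
estimate_specificity_sensitivity <- function(families, known_ids = character(),
                                             n_iter = 1000L, seed = NULL,
                                             ...) {
  stopifnot(length(families) > 0)
  if (n_iter < 100)
    warning("n_iter < 100 gives an unstable specificity estimate")
  with_seed(seed, {
    fp <- 0L
    for (it in seq_len(n_iter)) {
      fam <- families[[((it - 1L) %% length(families)) + 1L]]
      m <- align_rows_matrix(fam)
      perm <- sample.int(ncol(m))
      shuf <- apply(m[, perm, drop = FALSE], 1, collapse_chars)
      calls <- scan_igr_windows(shuf, igr_id = "rand", ...)
      if (nrow(calls) > 0) fp <- fp + 1L
    }
    detected <- names(families)[vapply(names(families), function(id) {
      nrow(scan_igr_windows(families[[id]], igr_id = id, ...)) > 0
    }, logical(1))]
    screen_performance(
      n_false_positive = fp, n_random = n_iter,
      n_known_detected = if (length(known_ids))
        length(intersect(detected, known_ids)) else NA_integer_,
      n_known = if (length(known_ids)) length(known_ids) else NA_integer_)
  })
}

#' Reference-anchored multiple alignment of an IGR family
#'
#' Each homolog is aligned globally to the reference sequence and projected
#' onto reference coordinates (homolog insertions relative to the reference
#' are dropped; deletions become gaps). Suited to closely related strain
#' families where indels are rare.
#'
#' @param ref reference sequence (character).
#' @param others named character vector of homologous sequences.
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @return named character vector of equal-length rows, reference first
#'   (named `"ref"` unless `others` is empty).
#' @export
align_family <- function(ref, others, match = 1, mismatch = -2, gap_open = 5,
                         gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  rows <- c(ref = toupper(ref))
  for (nm in names(others)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(toupper(others[[nm]])),
      subject = Biostrings::DNAString(toupper(ref)),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    rows[[nm]] <- collapse_chars(p[s != "-"])
  }
  rows
}
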