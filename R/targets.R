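#' Nearest-neighbour RNA/RNA stacking free energies
#'
#' Standard Watson-Crick stack free energies at 37 degrees C (kcal/mol),
#' indexed by the 5' pair (rows) and the adjacent 3' pair (columns), pairs
#' written sRNA-base then mRNA-base. Stacks involving one GU wobble pair use
#' a simplified -1.2 kcal/mol, two wobble pairs -0.4 kcal/mol.
#'
#' @return a 6x6 numeric matrix with dimnames
#'   `c("AU","UA","GC","CG","GU","UG")`.
#' @export
rna_stack_table <- function() {
  p <- c("AU", "UA", "GC", "CG", "GU", "UG")
  E <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  wc <- list(
    c("AU", "AU", -0.93), c("AU", "UA", -1.10),
    c("AU", "GC", -2.08), c("AU", "CG", -2.24),
    c("UA", "AU", -1.33), c("UA", "UA", -0.93),
    c("UA", "GC", -2.11), c("UA", "CG", -2.35),
    c("GC", "AU", -2.35), c("GC", "UA", -2.24),
    c("GC", "GC", -3.26), c("GC", "CG", -3.42),
    c("CG", "AU", -2.11), c("CG", "UA", -2.08),
    c("CG", "GC", -2.36), c("CG", "CG", -3.26))
  for (w in wc) E[w[1], w[2]] <- as.numeric(w[3])
  wob <- c("GU", "UG")
  E[wob, ] <- -1.2
  E[, wob] <- -1.2
  E[wob, wob] <- -0.4
  E
}

#' Hybridization energy of an sRNA-mRNA duplex, by two scorers
#'
#' `duplex_dp` finds the minimum-free-energy intermolecular duplex under the
#' nearest-neighbour stack table with duplex initiation `+init` kcal/mol and
#' interior bulges of at most `max_bulge` nt penalized `+bulge_penalty` each,
#' over interaction sites of at most `max_len` nt on either molecule.
#' `seed_extend` reports the best duplex anchored on a run of at least
#' `seed_len` consecutive perfect Watson-Crick pairs (no hit when no such
#' seed exists). sRNAs of 50 nt or shorter are excluded with a reason code,
#' mirroring the convention that trans-acting sRNAs under study exceed 50 nt.
#'
#' @param srna_seq,mrna_seq sequences (DNA or RNA alphabet).
#' @param max_len maximum interaction length (nt, default 60).
#' @param seed_len minimum perfect seed length for `seed_extend` (default 7).
#' @param min_srna_len minimum sRNA length (default 51).
#' @param stack stack table, see [rna_stack_table()].
#' @param init duplex initiation energy (kcal/mol).
#' @param bulge_penalty,max_bulge bulge cost per nt and maximum bulged nt
#'   between consecutive pairs.
#' @return `data.frame` with one row per scorer: scorer, energy (kcal/mol,
#'   `NA` when no duplex), srna_start/srna_end, mrna_start/mrna_end,
#'   excluded, reason.
#' @export
duplex_energy <- function(srna_seq, mrna_seq, max_len = 60L, seed_len = 7L,
                          min_srna_len = 51L, stack = rna_stack_table(),
                          init = 4.1, bulge_penalty = 3, max_bulge = 2L) {
  empty <- function(scorer, reason = NA_character_) {
    data.frame(scorer = scorer, energy = NA_real_, srna_start = NA_integer_,
               srna_end = NA_integer_, mrna_start = NA_integer_,
               mrna_end = NA_integer_, excluded = !is.na(reason),
               reason = reason, stringsAsFactors = FALSE)
  }
  if (nchar(srna_seq) < min_srna_len)
    return(rbind(empty("duplex_dp", "srna_too_short"),
                 empty("seed_extend", "srna_too_short")))
  stopifnot(nchar(mrna_seq) > 0)
  s <- seq_to_codes(srna_seq)
  m <- seq_to_codes(mrna_seq)
  as_row <- function(scorer, res) {
    if (is.na(res$energy[1])) return(empty(scorer))
    data.frame(scorer = scorer, energy = res$energy,
               srna_start = res$srna_start, srna_end = res$srna_end,
               mrna_start = res$mrna_start, mrna_end = res$mrna_end,
               excluded = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  }
  dp <- .duplex_dp_cpp(s, m, stack, init, bulge_penalty,
                       as.integer(max_len), as.integer(max_bulge))
  se <- .seed_extend_cpp(s, m, stack, init, as.integer(seed_len),
                         as.integer(max_len))
  rbind(as_row("duplex_dp", dp), as_row("seed_extend", se))
}

#' Empirical-null interaction probability
#'
#' The probability that the observed hybridization energy beats chance: the
#' fraction of `n_null` dinucleotide-shuffled copies of the sRNA whose best
#' duplex against the same mRNA is weaker (higher energy) than the observed
#' one. A degenerate null (all replicate energies identical) gives `NA`.
#'
#' @param srna_seq,mrna_seq sequences.
#' @param observed_energy energy to situate within the null (kcal/mol); a
#'   vector gives one probability per entry against the same null.
#' @param n_null number of shuffled replicates (>= 100 recommended).
#' @param seed optional RNG seed (local to this call).
#' @param scorer which scorer's energy forms the null.
#' @param ... duplex parameters passed to [duplex_energy()].
#' @return probability in `[0, 1]` per observed energy, or `NA`.
#' @export
interaction_probability <- function(srna_seq, mrna_seq, observed_energy,
                                    n_null = 100L, seed = NULL,
                                    scorer = "duplex_dp", ...) {
  null <- with_seed(seed, {
    sh <- dinuc_shuffle(srna_seq, n_null)
    vapply(sh, function(x) {
      e <- duplex_energy(x, mrna_seq, ...)
      e <- e$energy[e$scorer == scorer]
      if (is.na(e)) 0 else e   # no duplex found: counts as weakest
    }, numeric(1))
  })
  degenerate <- length(unique(null)) == 1L
  vapply(observed_energy, function(obs) {
    if (degenerate) NA_real_ else mean(null > obs)
  }, numeric(1))
}

#' Consensus sRNA-mRNA target calling
#'
#' A pair is a consensus target when both scorers report a hybridization
#' energy below `energy_cut` with an empirical-null probability above
#' `prob_cut` (each scorer is situated within its own shuffled-sRNA null),
#' and the two scorers agree on the interaction site
#' (their mRNA site intervals overlap by at least `min_site_overlap` nt --
#' agreement on the target alone, with the scorers pointing at unrelated
#' loci, is not treated as corroboration). The opposite-expression contrast
#' count is attached, and a
#' target is `supported` when it is a consensus target corroborated by
#' opposite expression in at least `min_oe` contrasts. sRNAs with at least
#' `global_regulator_min` consensus targets are flagged as putative global
#' regulators.
#'
#' @param pairs `data.frame` with columns `srna_id`, `mrna_id`.
#' @param srna_seqs,mrna_seqs named character vectors of sequences.
#' @param oe result of [opposite_expression()] (may be empty).
#' @param energy_cut,prob_cut thresholds (defaults -20 kcal/mol and 0.5).
#' @param n_null null size for [interaction_probability()].
#' @param seed optional RNG seed.
#' @param min_oe minimum OE contrasts for `supported` (default 2).
#' @param min_site_overlap minimum overlap (nt) of the two scorers' mRNA
#'   sites for consensus (default 1).
#' @param global_regulator_min consensus-target count flagging a global
#'   regulator.
#' @param ... duplex parameters passed to [duplex_energy()].
#' @return `data.frame` of class `target_calls`: srna_id, mrna_id,
#'   energy_duplex_dp, energy_seed_extend, probability, passes_energy,
#'   passes_probability, n_scorers_supporting, oe_contrast_count, consensus,
#'   supported, global_regulator.
#' @export
call_targets <- function(pairs, srna_seqs, mrna_seqs, oe = NULL,
                         energy_cut = -20, prob_cut = 0.5, n_null = 100L,
                         seed = NULL, min_oe = 2L, global_regulator_min = 10L,
                         min_site_overlap = 1L, ...) {
  stopifnot(all(c("srna_id", "mrna_id") %in% names(pairs)))
  if (!nrow(pairs)) {
    out <- data.frame(srna_id = character(), mrna_id = character(),
                      energy_duplex_dp = numeric(),
                      energy_seed_extend = numeric(), probability = numeric(),
                      probability_seed = numeric(),
                      passes_energy = logical(),
                      passes_probability = logical(),
                      n_scorers_supporting = integer(),
                      site_overlap = integer(), consensus = logical(),
                      excluded = logical(), oe_contrast_count = integer(),
                      supported = logical(), global_regulator = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("target_calls", "data.frame")
    return(out)
  }
  rows <- with_seed(seed, lapply(seq_len(nrow(pairs)), function(i) {
    sid <- pairs$srna_id[i]
    mid <- pairs$mrna_id[i]
    de <- duplex_energy(srna_seqs[[sid]], mrna_seqs[[mid]], ...)
    e_dp <- de$energy[de$scorer == "duplex_dp"]
    e_se <- de$energy[de$scorer == "seed_extend"]
    if (any(de$excluded))
      return(data.frame(srna_id = sid, mrna_id = mid,
                        energy_duplex_dp = NA_real_,
                        energy_seed_extend = NA_real_, probability = NA_real_,
                        probability_seed = NA_real_,
                        passes_energy = FALSE, passes_probability = FALSE,
                        n_scorers_supporting = 0L, site_overlap = 0L,
                        consensus = FALSE,
                        excluded = TRUE, stringsAsFactors = FALSE))
    n_support <- sum(c(e_dp, e_se) < energy_cut, na.rm = TRUE)
    passes_energy <- n_support == 2L
    prob_dp <- prob_se <- NA_real_
    if (passes_energy) {
      prob_dp <- interaction_probability(srna_seqs[[sid]], mrna_seqs[[mid]],
                                         e_dp, n_null = n_null,
                                         scorer = "duplex_dp", ...)
      prob_se <- interaction_probability(srna_seqs[[sid]], mrna_seqs[[mid]],
                                         e_se, n_null = n_null,
                                         scorer = "seed_extend", ...)
    }
    passes_prob <- !is.na(prob_dp) && prob_dp > prob_cut &&
      !is.na(prob_se) && prob_se > prob_cut
    dp_row <- de[de$scorer == "duplex_dp", ]
    se_row <- de[de$scorer == "seed_extend", ]
    site_ov <- if (anyNA(c(dp_row$mrna_start, se_row$mrna_start))) 0L else
      max(0L, min(dp_row$mrna_end, se_row$mrna_end) -
            max(dp_row$mrna_start, se_row$mrna_start) + 1L)
    data.frame(srna_id = sid, mrna_id = mid, energy_duplex_dp = e_dp,
               energy_seed_extend = e_se, probability = prob_dp,
               probability_seed = prob_se,
               passes_energy = passes_energy,
               passes_probability = passes_prob,
               n_scorers_supporting = n_support,
               site_overlap = site_ov,
               consensus = passes_energy && passes_prob &&
                 site_ov >= min_site_overlap,
               excluded = FALSE, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  oe_count <- integer(nrow(out))
  if (!is.null(oe) && nrow(oe)) {
    key <- paste(out$srna_id, out$mrna_id)
    okey <- paste(oe$srna_id, oe$mrna_id)
    hit <- match(key, okey)
    oe_count[!is.na(hit)] <- oe$oe_contrast_count[hit[!is.na(hit)]]
  }
  out$oe_contrast_count <- oe_count
  out$supported <- out$consensus & out$oe_contrast_count >= min_oe
  n_cons <- table(out$srna_id[out$consensus])
  out$global_regulator <- out$srna_id %in%
    names(n_cons)[n_cons >= global_regulator_min]
  class(out) <- c("target_calls", "data.frame")
  out
}
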