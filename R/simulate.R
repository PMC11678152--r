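#' Configuration of the synthetic study generator
#'
#' Defaults encode the emulated study design: a GC-rich (72%) reference
#' genome with non-overlapping genes, a family of 8 strains diverged at 5%
#' per site (indels at one tenth of that rate), 20 IGRs carrying planted
#' GC-rich hairpin sRNAs under five-fold reduced divergence with
#' compensatory stem substitutions, a panel of shuffled decoy IGRs that are
#' not conserved, and a four-time-point (24/48/72/96 h) by three-replicate
#' negative-binomial count design with planted differential expression
#' (|log2FC| = 3 at 72 and 96 h) and 10 sRNA-target pairs whose target mRNAs
#' carry an exact 20-nt antisense site and anti-correlated expression among
#' 500 decoy mRNAs.
#'
#' @param seed RNG seed driving every stochastic choice.
#' @param n_strains number of comparator strains.
#' @param genome_len reference genome length (nt).
#' @param n_genes number of non-overlapping genes.
#' @param gene_len,igr_len length ranges (nt) for genes and intergenic gaps.
#' @param gc background GC fraction.
#' @param divergence per-site substitution probability per strain.
#' @param conserved_locus_divergence_factor divergence multiplier inside
#'   planted sRNA loci.
#' @param indel_factor indel rate as a fraction of the substitution rate.
#' @param n_planted_srnas number of IGRs receiving a planted hairpin.
#' @param hairpin_stem,hairpin_loop planted hairpin geometry (bp / nt).
#' @param srna_flank flank (nt) around the hairpin defining the sRNA
#'   transcript.
#' @param n_shuffled_igrs IGRs scrambled per strain (non-conserved decoys);
#'   `NULL` sizes the panel so that the conserved non-planted IGRs number
#'   200.
#' @param time_points,n_reps count design.
#' @param nb_dispersion negative-binomial dispersion.
#' @param planted_log2fc planted absolute log2 fold change.
#' @param de_time_points time points carrying the planted shift.
#' @param n_target_pairs planted sRNA-mRNA target pairs.
#' @param n_decoy_mrnas decoy mRNAs without planted sites.
#' @param mrna_len mRNA length (nt).
#' @param site_len length (nt) of the planted antisense site.
#' @param n_noise_srnas sparse low-coverage decoy transcripts exercising the
#'   reliability filter.
#' @param n_compendium_samples samples in the broad expression compendium
#'   against which the reliability filter is applied (emulating a multi-study
#'   RNA-seq collection, distinct from the growth-curve samples).
#' @param base_mean_log,base_mean_sdlog log-normal base-mean parameters.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_strains = 8L, genome_len = 200000L,
                       n_genes = 240L, gene_len = c(400L, 700L),
                       igr_len = c(60L, 360L), gc = 0.72, divergence = 0.05,
                       conserved_locus_divergence_factor = 0.2,
                       indel_factor = 0.1, n_planted_srnas = 20L,
                       hairpin_stem = 10L, hairpin_loop = 4L,
                       srna_flank = 40L, n_shuffled_igrs = NULL,
                       time_points = c("24h", "48h", "72h", "96h"),
                       n_reps = 3L, nb_dispersion = 0.1, planted_log2fc = 3,
                       de_time_points = c("72h", "96h"),
                       n_target_pairs = 10L, n_decoy_mrnas = 500L,
                       mrna_len = 900L, site_len = 20L, n_noise_srnas = 30L,
                       n_compendium_samples = 40L,
                       base_mean_log = log(100), base_mean_sdlog = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_strains >= 1, cfg$n_genes >= 2, cfg$divergence >= 0,
            cfg$divergence <= 1, cfg$gc > 0, cfg$gc < 1,
            cfg$n_planted_srnas >= 0, cfg$hairpin_stem >= 4)
  class(cfg) <- "sim_config"
  cfg
}

# substitute characters at rate `rate` (uniform over the three other bases),
# then apply single-base indels at rate `indel_rate`
mutate_chars <- function(x, rate, indel_rate = 0, gc = 0.72) {
  n <- length(x)
  if (n == 0) return(x)
  bases <- c("A", "C", "G", "T")
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    repl <- sample(bases, sum(hit), replace = TRUE)
    same <- repl == x[hit]
    while (any(same)) {
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == x[hit]
    }
    x[hit] <- repl
  }
  if (indel_rate > 0) {
    ev <- stats::runif(n) < indel_rate
    if (any(ev)) {
      del <- ev & (stats::runif(n) < 0.5)
      ins <- ev & !del
      out <- vector("list", n)
      p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      for (i in seq_len(n)) {
        if (del[i]) out[[i]] <- character(0)
        else if (ins[i]) out[[i]] <- c(x[i], sample(bases, 1, prob = p))
        else out[[i]] <- x[i]
      }
      x <- unlist(out)
    }
  }
  x
}

#' Simulate a strain family with planted conserved structured sRNAs
#'
#' Builds a reference genome and annotation, plants GC-rich hairpins in
#' selected IGRs, and derives comparator strains by per-site substitution at
#' the configured divergence (reduced inside planted loci, with
#' pair-preserving compensatory stem swaps so that structure is conserved
#' beyond sequence identity) plus rare single-base indels. A panel of decoy
#' IGRs is independently scrambled in every strain and is therefore not
#' conserved. The same seed yields byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @return a list with `reference` (an `annotation_set`), `strains` (named
#'   list of `annotation_set`s), `igrs` (reference `igr_set`) and `truth`
#'   (planted sRNA loci with IGR-relative coordinates, conserved and
#'   shuffled IGR ids, sRNA transcript sequences).
#' @export
simulate_strain_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    glen <- sample(gene_lengths(cfg), cfg$n_genes, replace = TRUE)
    ilen <- sample(seq(cfg$igr_len[1], cfg$igr_len[2]), cfg$n_genes - 1L,
                   replace = TRUE)
    head_gap <- sample(seq(cfg$igr_len[1], cfg$igr_len[2]), 1)
    total <- head_gap + sum(glen) + sum(ilen)
    if (total > cfg$genome_len - 50L)
      stop("genes do not fit in the genome (need ", total, " of ",
           cfg$genome_len, " nt)")
    starts <- head_gap + cumsum(c(0L, glen[-cfg$n_genes] +
                                    ilen)) + 1L
    ends <- starts + glen - 1L
    genome_seq <- random_dna(cfg$genome_len, cfg$gc)
    genes <- data.frame(
      id = sprintf("g%03d", seq_len(cfg$n_genes)),
      replicon = "chr", start = starts, end = ends,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      kind = "CDS", source = "sim", stringsAsFactors = FALSE)
    ann <- load_annotation_set(c(chr = genome_seq), genes)
    igrs <- extract_igrs(ann)

    hlen <- 2L * cfg$hairpin_stem + cfg$hairpin_loop
    eligible <- igrs$id[igrs$length >= hlen + 24L]
    if (length(eligible) < cfg$n_planted_srnas)
      stop("not enough IGRs long enough for hairpin planting")
    planted_ids <- sort(sample(eligible, cfg$n_planted_srnas))
    gchars <- seq_chars(genome_seq)
    loci <- do.call(rbind, lapply(planted_ids, function(id) {
      row <- igrs[igrs$id == id, ]
      stem <- collapse_chars(sample(c("G", "C", "A", "T"), cfg$hairpin_stem,
                                    replace = TRUE,
                                    prob = c(0.45, 0.45, 0.05, 0.05)))
      loop <- random_dna(cfg$hairpin_loop, 0.3)
      hp <- paste0(stem, loop, revcomp(stem))
      off <- sample(10L:(row$length - hlen - 10L), 1)
      h_start <- row$start + off - 1L
      h_end <- h_start + hlen - 1L
      data.frame(igr_id = id, replicon = row$replicon,
                 igr_start = row$start, igr_end = row$end,
                 hairpin_start = h_start, hairpin_end = h_end,
                 hairpin_rel_start = off, hairpin_rel_end = off + hlen - 1L,
                 stem = stem, hairpin = hp, stringsAsFactors = FALSE)
    }))
    loci <- loci[order(loci$hairpin_start), , drop = FALSE]
    for (i in seq_len(nrow(loci)))
      gchars[loci$hairpin_start[i]:loci$hairpin_end[i]] <-
        seq_chars(loci$hairpin[i])
    genome_seq <- collapse_chars(gchars)
    ann <- load_annotation_set(c(chr = genome_seq), genes)
    igrs <- extract_igrs(ann)

    non_planted <- setdiff(igrs$id, planted_ids)
    n_shuf <- cfg$n_shuffled_igrs %||%
      max(0L, length(non_planted) - 200L)
    shuffled_ids <- sort(sample(non_planted, min(n_shuf,
                                                 length(non_planted))))
    srnas <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i, ]
      s_start <- max(l$igr_start, l$hairpin_start - cfg$srna_flank)
      s_end <- min(l$igr_end, l$hairpin_end + cfg$srna_flank)
      data.frame(srna_id = paste0("srna_", l$igr_id), igr_id = l$igr_id,
                 start = s_start, end = s_end,
                 sequence = substr(genome_seq, s_start, s_end),
                 stringsAsFactors = FALSE)
    }))

    # comparator strains, built segment-wise so coordinates stay exact
    seg_bounds <- sort(unique(c(1L, genes$start, genes$end + 1L,
                                loci$hairpin_start, loci$hairpin_end + 1L,
                                cfg$genome_len + 1L)))
    seg_start <- seg_bounds[-length(seg_bounds)]
    seg_end <- seg_bounds[-1] - 1L
    seg_locus <- findInterval(seg_start, loci$hairpin_start)
    in_locus <- seg_locus >= 1 &
      seg_start <= loci$hairpin_end[pmax(seg_locus, 1)]
    igr_of_seg <- rep(NA_character_, length(seg_start))
    igr_idx <- findInterval(seg_start, igrs$start)
    in_igr <- igr_idx >= 1 & seg_start <= igrs$end[pmax(igr_idx, 1)]
    igr_of_seg[in_igr] <- igrs$id[igr_idx[in_igr]]

    sub_rate <- cfg$divergence
    locus_rate <- cfg$divergence * cfg$conserved_locus_divergence_factor
    indel_rate <- cfg$divergence * cfg$indel_factor
    built <- lapply(seq_len(cfg$n_strains), function(k) {
      pieces <- vector("list", length(seg_start))
      swaps <- vector("list", length(seg_start))
      for (si in seq_along(seg_start)) {
        x <- gchars[seg_start[si]:seg_end[si]]
        if (in_locus[si]) {
          sw <- compensatory_swap(x, cfg$hairpin_stem, cfg$hairpin_loop,
                                  p_swap = min(0.6, cfg$divergence * 12))
          swaps[[si]] <- sw$swapped
          x <- mutate_chars(sw$x, locus_rate, 0, cfg$gc)
        } else if (!is.na(igr_of_seg[si]) &&
                   igr_of_seg[si] %in% shuffled_ids) {
          x <- sample(x)
        } else {
          x <- mutate_chars(x, sub_rate, indel_rate, cfg$gc)
        }
        pieces[[si]] <- x
      }
      lens <- lengths(pieces)
      new_seq <- collapse_chars(unlist(pieces))
      new_starts <- cumsum(c(0L, lens[-length(lens)])) + 1L
      # genes start at segment boundaries by construction
      gmap <- match(genes$start, seg_start)
      gene_new_start <- new_starts[gmap]
      gend_map <- match(genes$end + 1L, c(seg_start, cfg$genome_len + 1L))
      gene_new_end <- c(new_starts, nchar(new_seq) + 1L)[gend_map] - 1L
      gk <- genes
      gk$start <- gene_new_start
      gk$end <- gene_new_end
      locus_rows <- do.call(rbind, lapply(which(in_locus), function(si) {
        data.frame(strain = sprintf("strain%02d", k),
                   igr_id = loci$igr_id[seg_locus[si]],
                   start = new_starts[si],
                   end = new_starts[si] + lens[si] - 1L,
                   swapped = paste(swaps[[si]], collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      list(ann = load_annotation_set(c(chr = new_seq), gk),
           loci = locus_rows)
    })
    strains <- stats::setNames(lapply(built, `[[`, "ann"),
                               sprintf("strain%02d",
                                       seq_len(cfg$n_strains)))
    strain_loci <- do.call(rbind, lapply(built, `[[`, "loci"))

    truth <- list(
      planted_srna_loci = loci,
      planted_srnas = srnas,
      strain_loci = strain_loci,
      conserved_igrs = setdiff(igrs$id, shuffled_ids),
      shuffled_igrs = shuffled_ids,
      planted_igr_ids = planted_ids,
      config = cfg)
    list(reference = ann, strains = strains, igrs = igrs, truth = truth)
  })
}

gene_lengths <- function(cfg) seq(cfg$gene_len[1], cfg$gene_len[2])

# pair-preserving stem substitutions: swap G<->C (or A<->T) at a paired stem
# position and its partner, keeping the hairpin foldable; returns the
# mutated characters and the swapped positions
compensatory_swap <- function(x, stem, loop, p_swap = 0.6) {
  if (stats::runif(1) > p_swap)
    return(list(x = x, swapped = integer(0)))
  n_swap <- sample(1:2, 1)
  idx <- sample(seq_len(stem), n_swap)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  touched <- integer(0)
  for (i in idx) {
    j <- 2L * stem + loop + 1L - i  # partner position in the hairpin
    a <- x[i]
    if (!a %in% names(comp)) next
    x[i] <- comp[[a]]
    x[j] <- a
    touched <- c(touched, i, j)
  }
  list(x = x, swapped = sort(touched))
}

#' Simulate a count matrix with planted DE sRNAs and anti-correlated targets
#'
#' Counts are negative binomial over the configured time-course design with
#' log-normal base means and mild library-size variation. A subset of sRNAs
#' receives a `+planted_log2fc` (or `-`) mean shift at the configured late
#' time points; each has a target mRNA shifted oppositely at the same time
#' points and carrying an exact antisense site of `site_len` nt
#' (the reverse complement of an sRNA subsequence) mid-sequence. Sparse
#' noise transcripts exercise the reliability filter.
#'
#' @param cfg a [sim_config()].
#' @param srna_seqs optional named sRNA sequences (e.g. the planted
#'   transcripts of [simulate_strain_family()]); generated randomly when
#'   `NULL`.
#' @param seed RNG seed; defaults to `cfg$seed + 1` so the family and the
#'   counts use distinct streams.
#' @return list with `counts`, `design`, `lengths`, `categories`,
#'   `srna_seqs`, `mrna_seqs` and `truth` (planted DE features and target
#'   pairs).
#' @export
simulate_counts <- function(cfg = sim_config(), srna_seqs = NULL,
                            seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    if (is.null(srna_seqs)) {
      srna_seqs <- stats::setNames(
        vapply(seq_len(max(cfg$n_target_pairs, cfg$n_planted_srnas)),
               function(i) random_dna(120, cfg$gc), character(1)),
        sprintf("srna_%03d", seq_len(max(cfg$n_target_pairs,
                                         cfg$n_planted_srnas))))
    }
    stopifnot(length(srna_seqs) >= cfg$n_target_pairs)
    n_mrna <- cfg$n_decoy_mrnas + cfg$n_target_pairs
    mrna_seqs <- stats::setNames(
      vapply(seq_len(n_mrna), function(i) random_dna(cfg$mrna_len, cfg$gc),
             character(1)),
      sprintf("mrna_%03d", seq_len(n_mrna)))
    de_srnas <- sample(names(srna_seqs), cfg$n_target_pairs)
    target_mrnas <- sample(names(mrna_seqs), cfg$n_target_pairs)
    dir_up <- sample(c(TRUE, FALSE), cfg$n_target_pairs, replace = TRUE)
    pairs <- data.frame(srna_id = de_srnas, mrna_id = target_mrnas,
                        srna_direction = ifelse(dir_up, "up", "down"),
                        stringsAsFactors = FALSE)
    # plant exact antisense sites mid-CDS
    for (i in seq_len(nrow(pairs))) {
      s <- srna_seqs[[pairs$srna_id[i]]]
      p0 <- sample(seq_len(nchar(s) - cfg$site_len + 1L), 1)
      site <- revcomp(substr(s, p0, p0 + cfg$site_len - 1L))
      m <- mrna_seqs[[pairs$mrna_id[i]]]
      at <- nchar(m) %/% 2L
      substr(m, at, at + cfg$site_len - 1L) <- site
      mrna_seqs[[pairs$mrna_id[i]]] <- m
    }
    noise_ids <- if (cfg$n_noise_srnas > 0)
      sprintf("noise_%03d", seq_len(cfg$n_noise_srnas)) else character(0)
    feats <- c(names(srna_seqs), names(mrna_seqs), noise_ids)
    lens <- c(nchar(srna_seqs), nchar(mrna_seqs),
              rep(120L, length(noise_ids)))
    names(lens) <- feats
    categories <- stats::setNames(
      c(rep("novel", length(srna_seqs)), rep("CDS", length(mrna_seqs)),
        rep("novel", length(noise_ids))), feats)
    design <- expand.grid(replicate = seq_len(cfg$n_reps),
                          time = cfg$time_points, stringsAsFactors = FALSE)
    design$sample <- paste0(design$time, "_r", design$replicate)
    design <- design[, c("sample", "time", "replicate")]
    base <- stats::rlnorm(length(feats), cfg$base_mean_log,
                          cfg$base_mean_sdlog)
    names(base) <- feats
    base[c(pairs$srna_id, pairs$mrna_id)] <-
      pmax(base[c(pairs$srna_id, pairs$mrna_id)], 50)
    libsize <- stats::rlnorm(nrow(design), 0, 0.15)
    lfc <- stats::setNames(numeric(length(feats)), feats)
    lfc[pairs$srna_id] <- ifelse(dir_up, cfg$planted_log2fc,
                                 -cfg$planted_log2fc)
    lfc[pairs$mrna_id] <- -lfc[pairs$srna_id]
    counts <- matrix(0L, length(feats), nrow(design),
                     dimnames = list(feats, design$sample))
    for (j in seq_len(nrow(design))) {
      shift <- design$time[j] %in% cfg$de_time_points
      mu <- base * 2^(if (shift) lfc else 0) * libsize[j]
      counts[, j] <- stats::rnbinom(length(feats), mu = mu,
                                    size = 1 / cfg$nb_dispersion)
    }
    # sparse noise transcripts: a few reads in a few samples only
    for (id in noise_ids) {
      counts[id, ] <- 0L
      on_in <- sample(nrow(design), sample(2:6, 1))
      counts[id, on_in] <- stats::rpois(length(on_in), 5) + 1L
    }
    # broad compendium for the reliability filter: condition-to-condition
    # variability on top of the base means, sparse noise stays sparse
    ncs <- cfg$n_compendium_samples
    compendium <- matrix(0L, length(feats), ncs,
                         dimnames = list(feats, sprintf("lib%02d",
                                                        seq_len(ncs))))
    for (j in seq_len(ncs)) {
      cond <- stats::rlnorm(length(feats), 0, 0.5)
      compendium[, j] <- stats::rnbinom(length(feats), mu = base * cond,
                                        size = 1 / cfg$nb_dispersion)
    }
    for (id in noise_ids) {
      compendium[id, ] <- 0L
      on_in <- sample(ncs, sample(2:6, 1))
      compendium[id, on_in] <- stats::rpois(length(on_in), 5) + 1L
    }
    truth <- list(
      planted_de = data.frame(
        feature_id = c(pairs$srna_id, pairs$mrna_id),
        log2fc = c(lfc[pairs$srna_id], lfc[pairs$mrna_id]),
        row.names = NULL, stringsAsFactors = FALSE),
      planted_target_pairs = pairs,
      real_srna_ids = names(srna_seqs),
      noise_ids = noise_ids)
    list(counts = counts, compendium = compendium, design = design,
         lengths = lens, categories = categories, srna_seqs = srna_seqs,
         mrna_seqs = mrna_seqs, truth = truth)
  })
}

recovery_row <- function(stage, n_truth, n_calls, tp_calls, recovered) {
  precision <- if (n_calls > 0) tp_calls / n_calls else NA_real_
  recall <- if (n_truth > 0) recovered / n_truth else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(stage = stage, n_truth = n_truth, n_calls = n_calls,
             precision = precision, recall = recall, f1 = f1,
             stringsAsFactors = FALSE)
}

recovery_ids <- function(stage, called, truth_ids) {
  recovery_row(stage, length(truth_ids), length(called),
               sum(called %in% truth_ids),
               length(intersect(truth_ids, called)))
}

# locus stage: a planted locus is recovered when a call on the same IGR
# covers at least `min_frac` of its length; a call is true when it touches
# any planted locus
recovery_loci <- function(stage, calls, loci, min_frac = 0.5) {
  if (is.null(calls) || nrow(calls) == 0)
    return(recovery_row(stage, nrow(loci), 0L, 0L, 0L))
  overlap <- function(cs, ce, ls, le) pmax(0L, pmin(ce, le) - pmax(cs, ls) + 1L)
  rec <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    cc <- calls[calls$igr_id == l$igr_id, , drop = FALSE]
    if (!nrow(cc)) return(FALSE)
    any(overlap(cc$window_start, cc$window_end, l$hairpin_rel_start,
                l$hairpin_rel_end) >=
          min_frac * (l$hairpin_rel_end - l$hairpin_rel_start + 1L))
  }, logical(1))
  tp_call <- vapply(seq_len(nrow(calls)), function(i) {
    cc <- calls[i, ]
    ll <- loci[loci$igr_id == cc$igr_id, , drop = FALSE]
    if (!nrow(ll)) return(FALSE)
    any(overlap(cc$window_start, cc$window_end, ll$hairpin_rel_start,
                ll$hairpin_rel_end) > 0)
  }, logical(1))
  recovery_row(stage, nrow(loci), nrow(calls), sum(tp_call), sum(rec))
}

#' Precision/recall evaluation of pipeline outputs against ground truth
#'
#' Per stage: precision = true calls / calls, recall = recovered planted
#' items / planted items, F1 their harmonic mean. A planted structured locus
#' counts as recovered when a call on its IGR covers at least half of it.
#'
#' @param outputs a list with any of: `conservation` (ids called conserved),
#'   `structure` (structure-call `data.frame`), `srna_filter` (retained
#'   ids), `de` (ids called up or down), `targets` (`data.frame` with
#'   srna_id, mrna_id of supported calls).
#' @param truth ground truth (from the generator); must be non-empty.
#' @param min_frac minimum covered fraction for locus recovery.
#' @return `data.frame`: stage, n_truth, n_calls, precision, recall, f1.
#' @export
evaluate_recovery <- function(outputs, truth, min_frac = 0.5) {
  if (is.null(truth) || !length(truth)) stop("empty ground truth")
  rows <- list()
  if (!is.null(outputs$conservation))
    rows$conservation <- recovery_ids("conservation", outputs$conservation,
                                      truth$conserved_igrs)
  if (!is.null(outputs$structure))
    rows$structure <- recovery_loci("structure", outputs$structure,
                                    truth$planted_srna_loci, min_frac)
  if (!is.null(outputs$srna_filter))
    rows$srna_filter <- recovery_ids("srna_filter", outputs$srna_filter,
                                     truth$real_srna_ids)
  if (!is.null(outputs$de))
    rows$de <- recovery_ids("de", outputs$de, truth$planted_de$feature_id)
  if (!is.null(outputs$targets)) {
    tp <- truth$planted_target_pairs
    called <- paste(outputs$targets$srna_id, outputs$targets$mrna_id)
    rows$targets <- recovery_ids("targets", called,
                                 paste(tp$srna_id, tp$mrna_id))
  }
  if (!length(rows)) stop("no recognised pipeline outputs supplied")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
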