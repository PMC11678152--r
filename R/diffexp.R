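#' Median-of-ratios size factors
#'
#' Per-sample median of the ratios to the per-feature geometric mean,
#' computed over features with nonzero counts in every sample. Identical
#' columns get identical factors, and scaling a column by `c` scales its
#' factor by `c`.
#'
#' @param counts integer matrix, features x samples.
#' @return numeric vector of size factors (one per sample).
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use))
    stop("no feature has nonzero counts in every sample; ",
         "size factors are undefined")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - geo)))
}

# pooled within-group method-of-moments NB dispersion per feature
nb_dispersion_mom <- function(norm_counts, groups, floor = 0.01, cap = 20) {
  groups <- as.factor(groups)
  num <- 0
  den <- 0
  for (g in levels(groups)) {
    y <- norm_counts[, groups == g, drop = FALSE]
    ng <- ncol(y)
    if (ng < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    num <- num + (ng - 1) * (v - m)
    den <- den + (ng - 1) * m^2
  }
  alpha <- ifelse(den > 0, num / den, floor)
  pmin(pmax(alpha, floor), cap)
}

#' Differential expression over a growth curve (NB Wald test)
#'
#' A deliberately minimal negative-binomial engine: median-of-ratios size
#' factors, per-feature method-of-moments dispersion (floored at
#' `dispersion_floor`), and a delta-method Wald test of the log2 fold change
#' of each time point against the reference, with Benjamini-Hochberg
#' adjustment per contrast. Features are called `up` when
#' `log2fc >= lfc_cut` and `padj <= alpha`, `down` symmetrically, otherwise
#' `ns`.
#'
#' @param counts integer matrix, features x samples (row names = ids).
#' @param design `data.frame` with columns `sample` and `time` matching the
#'   columns of `counts`.
#' @param reference reference time point (default `"24h"`).
#' @param lfc_cut,alpha calling thresholds (defaults 2 and 0.01).
#' @param dispersion_floor lower bound on the NB dispersion.
#' @return `data.frame` of class `de_result`: feature_id, contrast,
#'   base_mean, log2fc, se, stat, pvalue, padj, call.
#' @export
de_test <- function(counts, design, reference = "24h", lfc_cut = 2,
                    alpha = 0.01, dispersion_floor = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(all(c("sample", "time") %in% names(design)),
            setequal(design$sample, colnames(counts)))
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  groups <- as.character(design$time)
  if (!reference %in% groups)
    stop("reference time point '", reference, "' absent from the design")
  tab <- table(groups)
  if (any(tab < 2))
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  ids <- rownames(counts) %||% paste0("f", seq_len(nrow(counts)))
  sf <- estimate_size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  alpha_nb <- nb_dispersion_mom(y, groups, floor = dispersion_floor)
  all_zero <- rowSums(counts) == 0
  ref_idx <- groups == reference
  m_ref <- rowMeans(y[, ref_idx, drop = FALSE])
  n_ref <- sum(ref_idx)
  out <- lapply(setdiff(unique(groups), reference), function(tp) {
    idx <- groups == tp
    m_tp <- rowMeans(y[, idx, drop = FALSE])
    n_tp <- sum(idx)
    # half-a-read continuity floor on group means with zero counts
    a <- pmax(m_ref, 0.5 / n_ref)
    b <- pmax(m_tp, 0.5 / n_tp)
    log2fc <- log2(b / a)
    se <- sqrt((1 / a + alpha_nb) / n_ref + (1 / b + alpha_nb) / n_tp) /
      log(2)
    stat <- log2fc / se
    pvalue <- 2 * stats::pnorm(-abs(stat))
    log2fc[all_zero] <- NA_real_
    se[all_zero] <- NA_real_
    stat[all_zero] <- NA_real_
    pvalue[all_zero] <- NA_real_
    padj <- stats::p.adjust(pvalue, method = "BH")
    call <- rep("ns", length(log2fc))
    call[!is.na(padj) & padj <= alpha & !is.na(log2fc) &
           log2fc >= lfc_cut] <- "up"
    call[!is.na(padj) & padj <= alpha & !is.na(log2fc) &
           log2fc <= -lfc_cut] <- "down"
    data.frame(feature_id = ids,
               contrast = paste0(tp, "-vs-", reference),
               base_mean = (m_ref + m_tp) / 2,
               log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
               padj = padj, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Opposite-expression (OE) pairs between sRNAs and mRNAs
#'
#' Counts, for every (sRNA, mRNA) pair, the contrasts in which the two carry
#' opposite up/down differential-expression calls, and reports pairs with at
#' least `min_contrasts` such contrasts.
#'
#' @param de_srna,de_mrna [de_test()] results over identical contrasts.
#' @param min_contrasts reporting threshold (default 2).
#' @return `data.frame`: srna_id, mrna_id, oe_contrast_count.
#' @export
opposite_expression <- function(de_srna, de_mrna, min_contrasts = 2L) {
  stopifnot(setequal(unique(de_srna$contrast), unique(de_mrna$contrast)))
  tallies <- new.env(parent = emptyenv())
  for (ct in unique(de_srna$contrast)) {
    s <- de_srna[de_srna$contrast == ct, , drop = FALSE]
    m <- de_mrna[de_mrna$contrast == ct, , drop = FALSE]
    combos <- rbind(
      expand.grid(srna = s$feature_id[s$call == "up"],
                  mrna = m$feature_id[m$call == "down"],
                  stringsAsFactors = FALSE),
      expand.grid(srna = s$feature_id[s$call == "down"],
                  mrna = m$feature_id[m$call == "up"],
                  stringsAsFactors = FALSE))
    if (!nrow(combos)) next
    keys <- paste(combos$srna, combos$mrna, sep = "\r")
    for (k in keys)
      assign(k, (if (exists(k, envir = tallies)) get(k, envir = tallies)
                 else 0L) + 1L, envir = tallies)
  }
  keys <- ls(envir = tallies)
  if (!length(keys))
    return(data.frame(srna_id = character(), mrna_id = character(),
                      oe_contrast_count = integer(), stringsAsFactors = FALSE))
  counts <- vapply(keys, get, integer(1), envir = tallies)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(srna_id = vapply(parts, `[`, "", 1),
                    mrna_id = vapply(parts, `[`, "", 2),
                    oe_contrast_count = counts, stringsAsFactors = FALSE)
  out <- out[out$oe_contrast_count >= min_contrasts, , drop = FALSE]
  out <- out[order(out$srna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
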