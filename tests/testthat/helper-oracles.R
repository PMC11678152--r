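# Independent oracles used to check the package's dynamic programs. These
# deliberately use naive exhaustive search / textbook DP written separately
# from the package implementation.

# all nested structures (lists of pair matrices) over seq[i..j]
enum_structures <- function(n, pairable, min_loop = 3L) {
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(matrix(integer(0), 0, 2)))
    out <- rec(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (!pairable[i, k]) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (a in left) for (b in right)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  rec(1L, n)
}

oracle_pair_energy <- function(a, b, energies = c(gc = -3, au = -2, gu = -1)) {
  ab <- paste0(a, b)
  if (ab %in% c("GC", "CG")) return(energies[["gc"]])
  if (ab %in% c("AT", "TA", "AU", "UA")) return(energies[["au"]])
  if (ab %in% c("GT", "TG", "GU", "UG")) return(energies[["gu"]])
  NA_real_
}

# exhaustive minimum energy over all nested structures; model "pair" scores
# every pair, model "stack" scores a pair only when (i-1, j+1) is also paired
oracle_enum_mfe <- function(seq, min_loop = 3L, model = "pair") {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  pairable <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j > i) pairable[i, j] <- !is.na(oracle_pair_energy(x[i], x[j]))
  structs <- enum_structures(n, pairable, min_loop)
  best <- 0
  for (s in structs) {
    if (!nrow(s)) next
    e <- 0
    for (r in seq_len(nrow(s))) {
      i <- s[r, 1]; j <- s[r, 2]
      if (model == "pair") {
        e <- e + oracle_pair_energy(x[i], x[j])
      } else {
        enclosed <- any(s[, 1] == i - 1 & s[, 2] == j + 1)
        if (enclosed) e <- e + oracle_pair_energy(x[i], x[j])
      }
    }
    if (e < best) best <- e
  }
  best
}

# textbook Smith-Waterman with affine gaps (penalties positive), score only
oracle_sw_score <- function(q, s, match = 1, mismatch = -2, gap_open = 5,
                            gap_extend = 2) {
  a <- strsplit(toupper(q), "")[[1]]
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)    # gap in s (consume a)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in q (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + sub)
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# independent copy of the Watson-Crick nearest-neighbour stack table,
# indexed "<5' pair><3' pair>" with pairs written sRNA base + mRNA base
oracle_stack_lookup <- c(
  "AU.AU" = -0.93, "AU.UA" = -1.10, "AU.GC" = -2.08, "AU.CG" = -2.24,
  "UA.AU" = -1.33, "UA.UA" = -0.93, "UA.GC" = -2.11, "UA.CG" = -2.35,
  "GC.AU" = -2.35, "GC.UA" = -2.24, "GC.GC" = -3.26, "GC.CG" = -3.42,
  "CG.AU" = -2.11, "CG.UA" = -2.08, "CG.GC" = -2.36, "CG.CG" = -3.26)

# hand-summed energy of a perfect (fully complementary, antiparallel) duplex:
# srna 5'->3' versus its exact reverse complement, initiation +4.1
oracle_perfect_duplex_energy <- function(srna, init = 4.1) {
  x <- strsplit(chartr("T", "U", toupper(srna)), "")[[1]]
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pairs <- paste0(x, comp[x])
  e <- init
  for (k in seq_len(length(x) - 1))
    e <- e + oracle_stack_lookup[[paste0(pairs[k], ".", pairs[k + 1])]]
  e
}

# naive six-frame longest-ORF scan (residues between start and stop codons)
oracle_longest_orf <- function(seq) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  best <- 0L
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    for (f in 0:2) {
      cods <- substring(s, seq(f + 1, nchar(s) - 2, by = 3),
                        seq(f + 3, nchar(s), by = 3))
      if (!length(cods)) next
      open <- NA
      for (i in seq_along(cods)) {
        if (cods[i] %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(open)) best <- max(best, i - open - 1L)
          open <- NA
        } else if (is.na(open) && cods[i] %in% c("ATG", "GTG")) open <- i
      }
    }
  }
  best
}

# naive IGR enumeration: sort delimiting genes, walk with a running maximum
# end, record every positive gap between consecutive delimiters
oracle_igrs <- function(genes, replicon_len) {
  g <- genes[order(genes$start, genes$end), , drop = FALSE]
  out <- NULL
  if (nrow(g) >= 2) {
    run_end <- g$end[1]
    for (i in 2:nrow(g)) {
      if (g$start[i] > run_end + 1) {
        out <- rbind(out, data.frame(start = run_end + 1,
                                     end = g$start[i] - 1))
      }
      run_end <- max(run_end, g$end[i])
    }
  }
  out
}

random_genome_layout <- function(n_genes, len = 5000) {
  # random, possibly overlapping gene set
  starts <- sort(sample.int(len - 100, n_genes))
  ends <- pmin(len, starts + sample(20:150, n_genes, replace = TRUE))
  data.frame(
    id = paste0("g", seq_len(n_genes)),
    replicon = "chr", start = starts, end = ends,
    strand = sample(c("+", "-"), n_genes, TRUE),
    kind = sample(c("CDS", "CDS", "tRNA", "rRNA"), n_genes, TRUE),
    stringsAsFactors = FALSE)
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- runif(length(x)) < rate
  x[hit] <- sample(c("A", "C", "G", "T"), sum(hit), TRUE)
  paste(x, collapse = "")
}

dinuc_counts <- function(s) {
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(substring(s, 1:(nchar(s) - 1), 2:nchar(s)), levels = lv))
}
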