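hairpin_seq <- function(stem_len = 12, loop = "AAAA", context = 60,
                        gc = 0.5) {
  stem <- paste(sample(c("G", "C"), stem_len, TRUE), collapse = "")
  hp <- paste0(stem, loop, revcomp(stem))
  flank <- context - nchar(hp)
  left <- rand_seq(ceiling(flank / 2), gc)
  right <- rand_seq(floor(flank / 2), gc)
  paste0(left, hp, right)
}

test_that("folding matches the stated examples and is never positive", {
  expect_equal(fold_mfe("AAAAAAA")$mfe, 0)
  expect_equal(nrow(fold_mfe("AAAAAAA")$pairs), 0)
  expect_equal(fold_mfe("GGGGAAAACCCC")$mfe, -12)
  set.seed(3)
  for (i in 1:25) expect_lte(fold_mfe(rand_seq(sample(5:60, 1)))$mfe, 0)
})

test_that("folding equals exhaustive enumeration for short sequences", {
  set.seed(4)
  for (i in 1:40) {
    s <- rand_seq(sample(4:12, 1), gc = runif(1, 0.3, 0.8))
    expect_equal(fold_mfe(s)$mfe, oracle_enum_mfe(s, model = "pair"),
                 info = s)
    expect_equal(fold_mfe(s, model = "stack")$mfe,
                 oracle_enum_mfe(s, model = "stack"), info = s)
  }
})

test_that("reported pairs are consistent with the reported energy", {
  set.seed(14)
  en <- pair_energies()
  for (i in 1:10) {
    s <- rand_seq(40, 0.7)
    res <- fold_mfe(s)
    x <- strsplit(s, "")[[1]]
    e <- sum(apply(res$pairs, 1, function(p)
      oracle_pair_energy(x[p[1]], x[p[2]], en)))
    if (nrow(res$pairs) == 0) e <- 0
    expect_equal(res$mfe, e)
    # nested, min-loop respected
    expect_true(all(res$pairs[, 2] - res$pairs[, 1] > 3))
  }
})

test_that("dinucleotide shuffles preserve the dinucleotide count vector", {
  set.seed(15)
  s <- rand_seq(80, 0.6)
  sh <- dinuc_shuffle(s, 50)
  ref <- dinuc_counts(s)
  for (x in sh) expect_equal(dinuc_counts(x), ref)
  expect_gt(length(unique(sh)), 1)
})

test_that("a homopolymer shuffles to itself and z degenerates to 0", {
  expect_equal(unique(dinuc_shuffle(strrep("A", 50), 5)), strrep("A", 50))
  expect_warning(z <- structure_z_score(strrep("A", 50), 10), "degenerate")
  expect_equal(z$z, 0)
})

test_that("a planted 12-bp hairpin in a 60-nt context has z <= -2", {
  set.seed(16)
  zs <- replicate(20, structure_z_score(hairpin_seq(), n_shuffles = 30)$z)
  expect_lte(median(zs), -2)
  expect_gte(mean(zs <= -2), 0.7)
})

test_that("sci is exactly 1 for identical rows and near 0 for unrelated", {
  rows <- rep(c(x = "GGCGCAAAAGCGCC"), 3)
  expect_identical(consensus_sci(rows)$sci, 1)
  set.seed(17)
  scis <- replicate(20, {
    al <- sapply(1:4, function(i) rand_seq(60, 0.5))
    consensus_sci(al)$sci
  })
  expect_lte(mean(scis), 0.3)
})

test_that("compensatory GC<->CG swaps keep sci high", {
  stem <- "GGCGCCGGCC"
  # rows with pair-preserving swaps at different stem positions
  base <- paste0("AATAA", stem, "GAAA", revcomp(stem), "AATAA")
  swap_pair <- function(s, i) {
    x <- strsplit(s, "")[[1]]
    a <- 5 + i                  # stem position in full sequence
    b <- 5 + 2 * nchar(stem) + 4 + 1 - i
    tmp <- x[a]; x[a] <- x[b]; x[b] <- tmp
    paste(x, collapse = "")
  }
  rows <- c(ref = base, s1 = swap_pair(base, 2), s2 = swap_pair(base, 5),
            s3 = swap_pair(base, 8))
  expect_gte(consensus_sci(rows)$sci, 0.8)
})

# mimic the generator's planted families: background divergence plus a
# pair-preserving compensatory swap in the hairpin stem
diverge_with_swap <- function(ref, hp_start, stem_len, loop_len, rate) {
  x <- strsplit(mutate_seq(substr(ref, 1, hp_start - 1), rate), "")[[1]]
  hp <- strsplit(substr(ref, hp_start,
                        hp_start + 2 * stem_len + loop_len - 1), "")[[1]]
  i <- sample(stem_len, 1)
  j <- 2 * stem_len + loop_len + 1 - i
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tmp <- hp[i]; hp[i] <- comp[[hp[i]]]; hp[j] <- tmp
  tail0 <- mutate_seq(substr(ref, hp_start + 2 * stem_len + loop_len,
                             nchar(ref)), rate)
  paste0(paste(x, collapse = ""), paste(hp, collapse = ""), tail0)
}

test_that("scan finds a planted conserved hairpin and reports its locus", {
  set.seed(18)
  stem <- paste(sample(c("G", "C"), 10, TRUE), collapse = "")
  hp <- paste0(stem, "TTCG", revcomp(stem))
  ref <- paste0(rand_seq(60, 0.7), hp, rand_seq(60, 0.7))
  fam <- c(ref = ref)
  for (k in 1:4)
    fam[paste0("s", k)] <- diverge_with_swap(ref, 61, 10, 4, 0.05)
  al <- align_family(fam[[1]], fam[-1])
  calls <- scan_igr_windows(al, igr_id = "t1", seed = 19)
  expect_gte(nrow(calls), 1)
  expect_true(any(calls$window_start <= 61 + 24 & calls$window_end >= 61))
  expect_true(all(calls$p_structured > 0.5))
})

test_that("column-shuffled alignments are almost never called", {
  set.seed(20)
  fp <- replicate(30, {
    base <- strsplit(rand_seq(120, 0.7), "")[[1]]
    rows <- sapply(1:5, function(i) {
      x <- base
      hit <- runif(120) < 0.05
      x[hit] <- sample(c("A", "C", "G", "T"), sum(hit), TRUE)
      paste(x, collapse = "")
    })
    names(rows) <- paste0("s", 1:5)
    perm <- sample.int(120)
    shuf <- sapply(rows, function(r)
      paste(strsplit(r, "")[[1]][perm], collapse = ""))
    nrow(scan_igr_windows(shuf, igr_id = "x")) > 0
  })
  expect_gte(mean(!fp), 0.95)
})

test_that("two separated hairpins in one IGR yield two calls", {
  set.seed(21)
  mk_hp <- function() {
    stem <- paste(sample(c("G", "C"), 10, TRUE), collapse = "")
    paste0(stem, "TTCG", revcomp(stem))
  }
  ref <- paste0(rand_seq(40, 0.7), mk_hp(), rand_seq(230, 0.7), mk_hp(),
                rand_seq(40, 0.7))
  fam <- c(ref = ref)
  for (k in 1:4) {
    s <- diverge_with_swap(ref, 41, 10, 4, 0.04)
    # swap in the second hairpin as well
    x <- strsplit(s, "")[[1]]
    i <- sample(10, 1)
    a <- 294 + i
    b <- 294 + 25 - i
    tmp <- x[a]
    x[a] <- chartr("ACGT", "TGCA", x[a])
    x[b] <- tmp
    fam[paste0("s", k)] <- paste(x, collapse = "")
  }
  al <- align_family(fam[[1]], fam[-1])
  calls <- scan_igr_windows(al, igr_id = "two", seed = 22)
  expect_gte(nrow(calls), 2)
})

test_that("terminator detection needs stem, loop and a downstream U-tail", {
  hits <- detect_terminators("AAAAGCGCGCTTTTGCGCGCTTTTTTTT")
  expect_equal(nrow(hits), 1)
  expect_gte(hits$stem_len, 4)
  expect_gte(hits$u_tail_len, 3)
  expect_true(hits$loop_len >= 3 && hits$loop_len <= 10)

  expect_equal(nrow(detect_terminators(strrep("A", 50))), 0)
  expect_equal(nrow(detect_terminators("AAAAGCGCGCTTTTGCGCGCAAAAAAAA")), 0)
})

test_that("screen performance encodes the specificity/sensitivity formulas", {
  perf <- screen_performance(n_false_positive = 21, n_random = 1000,
                             n_known_detected = 0, n_known = 0)
  expect_identical(perf$specificity, 1 - 21 / 1000)
  expect_equal(perf$specificity, 0.979)
  expect_equal(screen_performance(0, 100, 8, 10)$sensitivity, 0.8)
  expect_true(is.na(screen_performance(0, 100)$sensitivity))
})

test_that("a screen that rejects everything has specificity 1, sensitivity 0", {
  set.seed(23)
  fams <- lapply(1:3, function(i) {
    base <- rand_seq(80, 0.6)
    rows <- c(ref = base, s1 = mutate_seq(base, 0.05),
              s2 = mutate_seq(base, 0.05))
    rows
  })
  names(fams) <- paste0("f", 1:3)
  expect_warning(
    perf <- estimate_specificity_sensitivity(
      fams, known_ids = c("f1", "f2"), n_iter = 12, seed = 24,
      coefs = c(a = 0, b = 0, c = -10)),  # nothing can be positive
    "unstable")
  expect_equal(perf$specificity, 1.0)
  expect_equal(perf$sensitivity, 0.0)
  expect_equal(perf$n_false_positive, 0)
})

test_that("both-strand scanning reports the strand of the better score", {
  set.seed(25)
  stem <- paste(sample(c("G", "C"), 10, TRUE), collapse = "")
  hp <- paste0(stem, "TTCG", revcomp(stem))
  ref <- paste0(rand_seq(50, 0.7), hp, rand_seq(50, 0.7))
  fam <- c(ref = ref)
  for (k in 1:4) fam[paste0("s", k)] <- mutate_seq(ref, 0.04)
  al <- align_family(fam[[1]], fam[-1])
  calls <- scan_igr_windows(al, igr_id = "s", seed = 26)
  expect_true(all(calls$strand %in% c("+", "-")))
})
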