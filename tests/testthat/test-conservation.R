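test_that("self-alignment gives full coverage, identity 1 and a tiny evalue", {
  s <- rand_seq(200, gc = 0.6)
  h <- local_align(s, s)
  expect_equal(h$query_coverage, 1.0)
  expect_equal(h$identity, 1.0)
  expect_lt(h$evalue, 1e-5)
})

test_that("independent random sequences rarely reach evalue 1e-5", {
  set.seed(5)
  ev <- replicate(60, local_align(rand_seq(200), rand_seq(200))$evalue)
  expect_gte(mean(ev > 1e-5), 0.95)
})

test_that("appending an exactly matching block never decreases the score", {
  set.seed(6)
  for (i in 1:10) {
    q <- rand_seq(100); s <- rand_seq(120)
    blk <- rand_seq(50)
    s0 <- local_align(q, s)$score
    s1 <- local_align(paste0(q, blk), paste0(s, blk))$score
    expect_gte(s1, s0)
  }
})

test_that("alignment score matches a textbook Smith-Waterman oracle", {
  set.seed(8)
  for (i in 1:12) {
    q <- rand_seq(sample(30:60, 1))
    s <- if (i %% 2) mutate_seq(q, 0.15) else rand_seq(sample(30:60, 1))
    expect_equal(local_align(q, s)$score, oracle_sw_score(q, s))
  }
})

test_that("evalue is strictly decreasing in score at fixed lengths", {
  K <- 0.71; lambda <- 1.28
  ev <- function(sc) K * 200 * 300 * exp(-lambda * sc)
  expect_true(all(diff(ev(1:50)) < 0))
})

test_that("a planted copy forms an RBBH pair; thresholds exclude weak hits", {
  set.seed(9)
  ref <- stats::setNames(sapply(1:6, function(i) rand_seq(200, 0.6)),
                         paste0("igr_", 1:6))
  g2 <- stats::setNames(sapply(1:6, function(i) rand_seq(200, 0.6)),
                        paste0("s_", 1:6))
  g2[["s_3"]] <- ref[["igr_2"]]                       # exact copy
  g2[["s_5"]] <- substr(ref[["igr_4"]], 1, 130)       # coverage 0.65
  rb <- find_rbbh_pairs(ref, list(g2 = g2))$g2
  expect_true(any(rb$query == "igr_2" & rb$subject == "s_3"))
  expect_false(any(rb$query == "igr_4"))   # fails the 70% coverage rule
})

test_that("reciprocal-best pairs match an all-vs-all brute-force aligner", {
  set.seed(10)
  base <- sapply(1:5, function(i) rand_seq(150, 0.55))
  ref <- stats::setNames(base, paste0("r", 1:5))
  oth <- stats::setNames(c(sapply(base[1:4], mutate_seq, rate = 0.08),
                           rand_seq(150, 0.55)), paste0("o", 1:5))
  rb <- find_rbbh_pairs(ref, list(g = oth))$g

  score <- outer(seq_along(ref), seq_along(oth), Vectorize(function(i, j)
    oracle_sw_score(ref[[i]], oth[[j]])))
  oracle_pairs <- NULL
  for (i in seq_along(ref)) {
    j <- which.max(score[i, ])
    if (which.max(score[, j]) == i) {
      ev <- 0.71 * 150 * 150 * exp(-1.28 * score[i, j])
      if (ev < 1e-5)
        oracle_pairs <- rbind(oracle_pairs, c(names(ref)[i], names(oth)[j]))
    }
  }
  got <- rb[order(rb$query), c("query", "subject")]
  expect_equal(unname(as.matrix(got)), unname(oracle_pairs[order(oracle_pairs[, 1]), , drop = FALSE]))
})

test_that("reverse-complemented homologs are still found", {
  set.seed(12)
  ref <- stats::setNames(sapply(1:3, function(i) rand_seq(180, 0.6)),
                         paste0("r", 1:3))
  oth <- stats::setNames(c(revcomp(mutate_seq(ref[["r1"]], 0.05)),
                           rand_seq(180, 0.6)), c("o1", "o2"))
  rb <- find_rbbh_pairs(ref, list(g = oth))$g
  expect_true(any(rb$query == "r1" & rb$subject == "o1" & rb$strand == "-"))
})

test_that("conservation flips exactly at the minimum-strain boundary", {
  fake_hit <- function(q) data.frame(
    query = q, subject = paste0("x_", q), strand = "+", score = 100,
    evalue = 1e-30, query_coverage = 1, subject_coverage = 1, identity = 0.95,
    stringsAsFactors = FALSE)
  rbbh <- lapply(1:5, function(g) {
    rbind(if (g <= 4) fake_hit("igr_a") else NULL,
          if (g <= 3) fake_hit("igr_b") else NULL,
          fake_hit("igr_c"))
  })
  names(rbbh) <- paste0("g", 1:5)
  cons <- call_conserved(c("igr_a", "igr_b", "igr_c"), rbbh, min_strains = 4)
  rec <- cons$records
  expect_true(rec$conserved[rec$igr_id == "igr_a"])    # present in 4
  expect_false(rec$conserved[rec$igr_id == "igr_b"])   # present in 3
  expect_true(rec$conserved[rec$igr_id == "igr_c"])    # present in all 5
  expect_equal(cons$profile$n_igrs[cons$profile$genomes_with_homolog == 5], 1)
  expect_error(call_conserved(c("igr_a"), rbbh, min_strains = 6),
               "exceeds")
})

test_that("RBBH symmetry: swapping roles yields the mirrored pairs", {
  set.seed(13)
  a <- stats::setNames(sapply(1:4, function(i) rand_seq(160, 0.55)),
                       paste0("a", 1:4))
  b <- stats::setNames(sapply(a[c(1, 3)], mutate_seq, rate = 0.06),
                       c("b1", "b2"))
  fwd <- find_rbbh_pairs(a, list(g = b))$g
  rev <- find_rbbh_pairs(b, list(g = a))$g
  expect_setequal(paste(fwd$query, fwd$subject),
                  paste(rev$subject, rev$query))
})
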