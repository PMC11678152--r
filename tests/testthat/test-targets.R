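rna_comp <- function(s) revcomp(s)  # DNA-level reverse complement

test_that("duplex energy of perfect duplexes matches the hand-summed table", {
  set.seed(50)
  for (i in 1:20) {
    frag <- rand_seq(sample(10:25, 1), gc = runif(1, 0.4, 0.9))
    # flanks chosen so the perfect run cannot extend by accident:
    # sRNA flanks (CA repeats) cannot pair with the all-A mRNA flanks
    srna <- paste0(strrep("CA", 15), frag, strrep("CA", 15))
    mrna <- paste0(strrep("A", 40), rna_comp(frag), strrep("A", 40))
    de <- duplex_energy(srna, mrna)
    exp_e <- oracle_perfect_duplex_energy(frag)
    expect_equal(de$energy[de$scorer == "seed_extend"], exp_e,
                 tolerance = 0.01, info = frag)
    expect_lte(de$energy[de$scorer == "duplex_dp"], exp_e + 0.01)
  }
})

test_that("GC-rich 25-nt complements clear -20 kcal/mol with both scorers", {
  set.seed(51)
  frag <- paste(sample(c("G", "C"), 25, TRUE), collapse = "")
  srna <- paste0(rand_seq(30, 0.3), frag, rand_seq(30, 0.3))
  mrna <- paste0(strrep("A", 50), rna_comp(frag), strrep("A", 50))
  de <- duplex_energy(srna, mrna)
  expect_true(all(de$energy <= -20))
})

test_that("without a 7-mer perfect seed, seed_extend reports no hit", {
  srna <- paste0(strrep("GA", 15), strrep("CT", 15))  # 60 nt
  mrna <- strrep("GGGAAA", 30)  # no 7-mer complement run
  de <- duplex_energy(srna, mrna)
  expect_true(is.na(de$energy[de$scorer == "seed_extend"]))
})

test_that("sRNAs must exceed 50 nt; the boundary is exact", {
  m <- rand_seq(200, 0.6)
  de50 <- duplex_energy(rand_seq(50, 0.6), m)
  expect_true(all(de50$excluded))
  expect_equal(unique(de50$reason), "srna_too_short")
  de51 <- duplex_energy(rand_seq(51, 0.6), m)
  expect_false(any(de51$excluded))
})

test_that("interaction sites never exceed the 60-nt maximum", {
  set.seed(52)
  frag <- paste(sample(c("G", "C", "A", "T"), 80, TRUE,
                       prob = c(.4, .4, .1, .1)), collapse = "")
  srna <- frag  # 80-nt perfect complement available
  mrna <- paste0(strrep("A", 30), rna_comp(frag), strrep("A", 30))
  de <- duplex_energy(srna, mrna)
  spans_s <- de$srna_end - de$srna_start + 1
  spans_m <- de$mrna_end - de$mrna_start + 1
  expect_true(all(spans_s <= 60))
  expect_true(all(spans_m <= 60))
})

test_that("appending a complementary stack never raises the dp energy", {
  set.seed(53)
  frag <- "GGCGC"
  e_prev <- Inf
  for (k in 1:8) {
    fr <- paste0(frag, strrep("GC", k))
    srna <- paste0(rand_seq(25, 0.3), fr, rand_seq(25, 0.3))
    mrna <- paste0(strrep("A", 30), rna_comp(fr), strrep("A", 30))
    de <- duplex_energy(srna, mrna)
    e <- de$energy[de$scorer == "duplex_dp"]
    expect_lte(e, e_prev + 1e-9)
    e_prev <- e
  }
})

test_that("probability is high for planted sites and NA when degenerate", {
  set.seed(54)
  frag <- paste(sample(c("G", "C"), 22, TRUE), collapse = "")
  srna <- paste0(rand_seq(40, 0.6), frag, rand_seq(40, 0.6))
  mrna <- paste0(rand_seq(100, 0.5), rna_comp(frag), rand_seq(100, 0.5))
  de <- duplex_energy(srna, mrna)
  p <- interaction_probability(srna, mrna,
                               de$energy[de$scorer == "duplex_dp"],
                               n_null = 60, seed = 55)
  expect_gte(p, 0.9)
  # homopolymer sRNA shuffles to itself: degenerate null
  expect_true(is.na(interaction_probability(strrep("G", 60), strrep("C", 80),
                                            observed_energy = -50,
                                            n_null = 10, seed = 56)))
})

test_that("consensus requires both scorers, site agreement and probability", {
  set.seed(57)
  frag <- paste(sample(c("G", "C"), 22, TRUE), collapse = "")
  srna <- paste0(rand_seq(40, 0.55), frag, rand_seq(40, 0.55))
  good_m <- paste0(rand_seq(80, 0.5), rna_comp(frag), rand_seq(80, 0.5))
  bad_m <- rand_seq(180, 0.3)   # AT-rich: weak duplexes only
  srnas <- c(s1 = srna)
  mrnas <- c(good = good_m, bad = bad_m)
  oe <- data.frame(srna_id = c("s1", "s1"), mrna_id = c("good", "bad"),
                   oe_contrast_count = c(2L, 2L), stringsAsFactors = FALSE)
  tc <- call_targets(oe[, 1:2], srnas, mrnas, oe = oe, seed = 58)
  expect_true(tc$consensus[tc$mrna_id == "good"])
  expect_true(tc$supported[tc$mrna_id == "good"])
  expect_false(tc$consensus[tc$mrna_id == "bad"])
  # internal consistency of the gate logic
  expect_equal(tc$consensus,
               tc$passes_energy & tc$passes_probability &
                 tc$site_overlap >= 1)
  expect_equal(tc$supported, tc$consensus & tc$oe_contrast_count >= 2)
})

test_that("short sRNAs propagate exclusion through target calling", {
  srnas <- c(tiny = rand_seq(45, 0.6))
  mrnas <- c(m = rand_seq(150, 0.6))
  tc <- call_targets(data.frame(srna_id = "tiny", mrna_id = "m"),
                     srnas, mrnas)
  expect_true(tc$excluded)
  expect_false(tc$consensus)
})

test_that("global regulators are flagged by consensus-target count", {
  set.seed(59)
  frag <- paste(sample(c("G", "C"), 24, TRUE), collapse = "")
  srna <- paste0(rand_seq(30, 0.55), frag, rand_seq(30, 0.55))
  mrnas <- stats::setNames(lapply(1:3, function(i)
    paste0(rand_seq(60, 0.5), rna_comp(frag), rand_seq(60, 0.5))),
    paste0("m", 1:3))
  pairs <- data.frame(srna_id = "s", mrna_id = names(mrnas),
                      stringsAsFactors = FALSE)
  tc <- call_targets(pairs, c(s = srna), unlist(mrnas), seed = 60,
                     global_regulator_min = 3)
  expect_true(all(tc$global_regulator == (sum(tc$consensus) >= 3)))
})
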