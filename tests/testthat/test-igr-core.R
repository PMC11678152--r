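toy_ann <- function(genes, len = 400) {
  load_annotation_set(c(chr = strrep("ACGT", ceiling(len / 4))[1]), genes)
}

gene <- function(id, start, end, strand = "+", kind = "CDS") {
  data.frame(id = id, replicon = "chr", start = start, end = end,
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

test_that("IGRs are the gaps between consecutive delimiting features", {
  ann <- toy_ann(rbind(gene("g1", 1, 100, "+"), gene("g2", 151, 300, "-")))
  ig <- extract_igrs(ann)
  expect_equal(nrow(ig), 1)
  expect_equal(ig$start, 101)
  expect_equal(ig$end, 150)
  expect_equal(ig$length, 50)
  expect_equal(ig$orientation_class, "DT")

  # abutting genes leave no gap
  ann2 <- toy_ann(rbind(gene("g1", 1, 100), gene("g2", 101, 300)))
  expect_equal(nrow(extract_igrs(ann2)), 0)

  ann3 <- toy_ann(rbind(gene("g1", 1, 100), gene("g2", 120, 200),
                        gene("g3", 250, 300)))
  expect_equal(extract_igrs(ann3)$length, c(19, 49))
})

test_that("terminal regions are excluded by default, included on request", {
  ann <- toy_ann(rbind(gene("g1", 50, 100), gene("g2", 150, 300)))
  expect_equal(nrow(extract_igrs(ann)), 1)
  with_term <- extract_igrs(ann, include_terminal = TRUE)
  expect_equal(nrow(with_term), 3)
  expect_true(any(is.na(with_term$orientation_class)))
})

test_that("nested and overlapping genes never produce negative gaps", {
  ann <- toy_ann(rbind(gene("g1", 1, 200), gene("g2", 50, 120),
                       gene("g3", 150, 250), gene("g4", 300, 350)))
  ig <- extract_igrs(ann)
  expect_equal(nrow(ig), 1)
  expect_equal(ig$start, 251)
  expect_equal(ig$end, 299)
  expect_equal(ig$left_gene, "g3")
})

test_that("only CDS/tRNA/rRNA delimit IGRs", {
  ann <- toy_ann(rbind(gene("g1", 1, 100), gene("s1", 120, 140,
                                                kind = "putative_sRNA"),
                       gene("g2", 200, 300)))
  ig <- extract_igrs(ann)
  expect_equal(nrow(ig), 1)
  expect_equal(c(ig$start, ig$end), c(101, 199))
})

test_that("orientation classification is total over the four strand pairs", {
  expect_equal(classify_orientation("+", "-"), "DT")
  expect_equal(classify_orientation("-", "+"), "DP")
  expect_equal(classify_orientation("+", "+"), "CO_F")
  expect_equal(classify_orientation("-", "-"), "CO_R")
  expect_error(classify_orientation(".", "+"))
})

test_that("gc content handles plain and degenerate sequences", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("GANNC"), 2 / 3)
  expect_true(is.na(gc_content("NNNN")))
})

test_that("gene, IGR and terminal-gap lengths tile the replicon", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    lens <- sample(10:60, n, TRUE)
    gaps <- sample(0:50, n, TRUE)  # gap 0 = abutting genes, no IGR
    starts <- integer(n)
    ends <- integer(n)
    starts[1] <- gaps[1] + 1
    ends[1] <- starts[1] + lens[1] - 1
    for (i in seq_len(n)[-1]) {
      starts[i] <- ends[i - 1] + gaps[i] + 1
      ends[i] <- starts[i] + lens[i] - 1
    }
    if (max(ends) > 1200) next
    ann <- load_annotation_set(
      c(chr = strrep("ACGT", 300)),
      data.frame(id = paste0("g", 1:n), replicon = "chr", start = starts,
                 end = ends, strand = "+", kind = "CDS",
                 stringsAsFactors = FALSE))
    ig <- extract_igrs(ann)
    term <- (starts[1] - 1) + (1200 - ends[n])
    expect_equal(sum(ends - starts + 1) + sum(ig$length) + term, 1200)
  }
})

test_that("coding potential reports the longest ORF in residues", {
  expect_equal(coding_call("CCCCCCCCCCCC")$longest_orf_aa, 0)
  orf113 <- paste0("ATG", strrep("GCT", 113), "TAA")
  cc <- coding_call(orf113)
  expect_equal(cc$longest_orf_aa, 113)
  expect_true(cc$is_coding)
  expect_false(coding_call(orf113, min_aa = 200)$is_coding)

  # reverse-strand ORF
  fwd <- paste0("ATG", strrep("GGC", 30), "TGA")
  rev <- revcomp(fwd)
  expect_equal(coding_call(rev)$longest_orf_aa, 30)
})

test_that("longest ORF matches a brute-force six-frame oracle", {
  set.seed(11)
  for (i in 1:30) {
    s <- rand_seq(sample(60:300, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(coding_call(s)$longest_orf_aa, oracle_longest_orf(s),
                 info = s)
  }
})
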