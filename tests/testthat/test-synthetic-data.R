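small_cfg <- function(seed = 3) {
  sim_config(seed = seed, n_strains = 3, genome_len = 30000, n_genes = 30,
             n_planted_srnas = 4, n_shuffled_igrs = 5, n_target_pairs = 3,
             n_decoy_mrnas = 20, n_noise_srnas = 5)
}

test_that("the generator is byte-identical under a fixed seed", {
  a <- simulate_strain_family(small_cfg())
  b <- simulate_strain_family(small_cfg())
  expect_identical(as.character(a$reference$genome),
                   as.character(b$reference$genome))
  expect_identical(a$truth$planted_srna_loci, b$truth$planted_srna_loci)
  for (k in seq_along(a$strains)) {
    expect_identical(as.character(a$strains[[k]]$genome),
                     as.character(b$strains[[k]]$genome))
    expect_identical(a$strains[[k]]$features, b$strains[[k]]$features)
  }
  ca <- simulate_counts(small_cfg())
  cb <- simulate_counts(small_cfg())
  expect_identical(ca$counts, cb$counts)
  expect_identical(ca$mrna_seqs, cb$mrna_seqs)
})

test_that("zero divergence reproduces the reference exactly", {
  cfg <- sim_config(seed = 4, n_strains = 2, genome_len = 30000,
                    n_genes = 30, divergence = 0, n_planted_srnas = 2,
                    n_shuffled_igrs = 0)
  fam <- simulate_strain_family(cfg)
  expect_identical(as.character(fam$strains[[1]]$genome),
                   as.character(fam$reference$genome))
})

test_that("emitted annotations validate and round-trip through files", {
  fam <- simulate_strain_family(small_cfg())
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_features_gff3(fam$strains[[1]], gff)
  Biostrings::writeXStringSet(fam$strains[[1]]$genome, fa)
  ann <- load_annotation_set(fa, gff)
  expect_equal(ann$features[, c("start", "end", "strand")],
               fam$strains[[1]]$features[, c("start", "end", "strand")])
})

test_that("planted loci diverge less than the background in every strain", {
  fam <- simulate_strain_family(sim_config(seed = 6, n_strains = 4,
                                           genome_len = 60000, n_genes = 60,
                                           n_planted_srnas = 8,
                                           n_shuffled_igrs = 0))
  loci <- fam$truth$planted_srna_loci
  sl <- fam$truth$strain_loci
  ref_igrs <- fam$igrs
  planted <- fam$truth$planted_igr_ids
  pid <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b))
    Biostrings::pid(pa) / 100
  }
  for (k in names(fam$strains)) {
    genome_k <- as.character(fam$strains[[k]]$genome[["chr"]])
    rows <- sl[sl$strain == k, , drop = FALSE]
    # per-site identity of the planted loci, excluding the pair-preserving
    # compensatory swap positions (structure-conserving exchanges, not
    # substitutions of the divergence process)
    match_n <- 0
    site_n <- 0
    for (r in seq_len(nrow(rows))) {
      l <- loci[loci$igr_id == rows$igr_id[r], ]
      ref_chars <- strsplit(substr(as.character(fam$reference$genome[["chr"]]),
                                   l$hairpin_start, l$hairpin_end), "")[[1]]
      str_chars <- strsplit(substr(genome_k, rows$start[r], rows$end[r]),
                            "")[[1]]
      swapped <- as.integer(strsplit(rows$swapped[r], ",")[[1]])
      keep <- setdiff(seq_along(ref_chars), swapped)
      match_n <- match_n + sum(ref_chars[keep] == str_chars[keep])
      site_n <- site_n + length(keep)
    }
    id_locus <- match_n / site_n
    st_igrs <- extract_igrs(fam$strains[[k]])
    idx <- match(ref_igrs$id, st_igrs$id)
    bg <- which(!ref_igrs$id %in% planted)
    id_bg <- mean(sapply(bg[seq(1, length(bg), length.out = 15)], function(i)
      pid(ref_igrs$sequence[i], st_igrs$sequence[idx[i]])))
    expect_gt(id_locus, id_bg)
  }
})

test_that("shuffled decoy IGRs are not conserved, the rest are", {
  fam <- simulate_strain_family(small_cfg(seed = 8))
  igrs_oth <- lapply(fam$strains, extract_igrs)
  rb <- find_rbbh_pairs(fam$igrs, igrs_oth)
  cons <- call_conserved(fam$igrs, rb, min_strains = 3)
  rec <- cons$records
  expect_true(all(!rec$conserved[rec$igr_id %in% fam$truth$shuffled_igrs]))
  conserved_frac <- mean(rec$conserved[rec$igr_id %in%
                                         fam$truth$conserved_igrs])
  expect_gte(conserved_frac, 0.9)
})

test_that("planted counts carry the configured fold change in expectation", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_counts(cfg)
  de_feats <- sim$truth$planted_de
  late <- sim$design$sample[sim$design$time %in% cfg$de_time_points]
  early <- sim$design$sample[!sim$design$time %in% cfg$de_time_points]
  obs <- log2(rowMeans(sim$counts[de_feats$feature_id, late, drop = FALSE]) /
                rowMeans(sim$counts[de_feats$feature_id, early,
                                    drop = FALSE]))
  expect_equal(mean(abs(obs)), cfg$planted_log2fc, tolerance = 0.5)
  expect_equal(sign(obs), sign(de_feats$log2fc), ignore_attr = TRUE)
  expect_true(all(colSums(sim$counts) > 0))
})

test_that("target mRNAs carry an exact antisense site to their sRNA", {
  sim <- simulate_counts(small_cfg(seed = 10))
  for (i in seq_len(nrow(sim$truth$planted_target_pairs))) {
    p <- sim$truth$planted_target_pairs[i, ]
    de <- duplex_energy(sim$srna_seqs[[p$srna_id]],
                        sim$mrna_seqs[[p$mrna_id]])
    se <- de[de$scorer == "seed_extend", ]
    expect_gte(se$srna_end - se$srna_start + 1, small_cfg(seed = 10)$site_len)
  }
})

test_that("a zero planted fold change centres group log-ratios on zero", {
  cfg <- small_cfg(seed = 11)
  cfg$planted_log2fc <- 0
  sim <- simulate_counts(cfg)
  late <- sim$design$sample[sim$design$time %in% cfg$de_time_points]
  early <- sim$design$sample[!sim$design$time %in% cfg$de_time_points]
  keep <- rowMeans(sim$counts) > 20
  obs <- log2((rowMeans(sim$counts[keep, late]) + 0.5) /
                (rowMeans(sim$counts[keep, early]) + 0.5))
  expect_lt(abs(mean(obs)), 0.2)
})

test_that("recovery evaluation implements precision/recall arithmetic", {
  truth <- list(conserved_igrs = c("a", "b", "c", "d"))
  perfect <- evaluate_recovery(list(conservation = c("a", "b", "c", "d")),
                               truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  nothing <- evaluate_recovery(list(conservation = character(0)), truth)
  expect_equal(nothing$recall, 0)
  expect_true(is.na(nothing$precision))
  half <- evaluate_recovery(list(conservation = c("a", "b")), truth)
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)
  expect_error(evaluate_recovery(list(conservation = "a"), list()),
               "empty")
})
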