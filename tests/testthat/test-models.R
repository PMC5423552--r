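# Theoretical nanospectrum models: MV, SVR, RF, and error profiling.

test_that("mv_spectrum follows the prefix/window/suffix schedule", {
  v <- mv_spectrum("KLMNP", k = 3)
  expect_length(v, 7)
  expected <- c(mean(aa_volume("K")),
                mean(aa_volume(c("K", "L"))),
                mean(aa_volume(c("K", "L", "M"))),
                mean(aa_volume(c("L", "M", "N"))),
                mean(aa_volume(c("M", "N", "P"))),
                mean(aa_volume(c("N", "P"))),
                mean(aa_volume("P")))
  expect_equal(v, expected)
  expect_equal(protein_windows("KLMNP", k = 3),
               c("K", "KL", "KLM", "LMN", "MNP", "NP", "P"))
  # degenerate cases
  expect_equal(mv_spectrum(strrep("A", 6), k = 4),
               rep(unname(aa_volume("A")), 9))
  expect_equal(mv_spectrum("KLMNP", k = 1), unname(aa_volume(c("K", "L", "M", "N", "P"))))
  expect_error(mv_spectrum("KL", k = 4), "shorter than window")
})

test_that("mv_spectrum matches the exhaustive substring-mean oracle", {
  # every protein of length <= 5 over a 4-letter alphabet spanning all
  # groups, every k <= 4 (longer lengths are spot-checked below)
  for (len in 1:5) {
    seqs <- all_sequences(len, TEST_ALPHABET)
    for (k in seq_len(min(4, len))) {
      for (s in seqs) expect_equal(mv_spectrum(s, k), mv_oracle(s, k))
    }
  }
  # random spot checks at lengths 6-8 over the full alphabet
  set.seed(17)
  aas <- aa_properties()$residue
  for (i in 1:60) {
    len <- sample(6:8, 1)
    s <- paste(sample(aas, len, replace = TRUE), collapse = "")
    k <- sample(1:4, 1)
    expect_equal(mv_spectrum(s, k), mv_oracle(s, k))
  }
})

test_that("all models output the L + k - 1 alignment length", {
  prot <- random_protein(68, seed = 31)
  expect_length(mv_spectrum(prot), 71)
  pairs <- labelled_pairs(random_protein(60, seed = 32), window_mean_volume)
  svr <- train_svr(pairs)
  rf <- train_rf(augment_permute(pairs, 3, seed = 1), seed = 1)
  expect_length(svr_spectrum(svr, prot), 71)
  expect_length(rf_spectrum(rf, prot), 71)
  expect_length(discretize(rnorm(500), nchar(prot) + 3), 71)
})

test_that("SVR trained on mean-volume labels reproduces the MV response", {
  pairs <- do.call(rbind, lapply(41:43, function(s)
    labelled_pairs(random_protein(150, seed = s), window_mean_volume)))
  svr <- train_svr(pairs)
  cors <- vapply(44:48, function(s) {
    h <- random_protein(80, seed = s)
    cor(svr_spectrum(svr, h), mv_spectrum(h))
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
  held_out <- random_protein(80, seed = 44)
  pred <- svr_spectrum(svr, held_out)
  # at the composition level the learned response tracks the closed-form
  # conditional mean volume (composition counts weighted by group means)
  comps <- enumerate_compositions(4, 4)
  colnames(comps) <- VOLUME_GROUPS
  tab <- aa_properties()
  gmeans <- tapply(tab$volume_nm3, as.character(tab$group), mean)
  cond <- as.numeric(comps %*% gmeans[VOLUME_GROUPS] / 4)
  expect_gt(cor(predict(svr$fit, comps), cond), 0.95)
  # determinism: same model, same protein, identical output
  expect_identical(pred, svr_spectrum(svr, held_out))
  expect_error(train_svr(pairs[0, ]), "empty")
})

test_that("SVR predictions depend only on window composition", {
  pairs <- labelled_pairs(random_protein(150, seed = 43), window_mean_volume)
  svr <- train_svr(pairs)
  prot <- random_protein(40, seed = 44)
  r <- strsplit(prot, "")[[1]]
  # permute an interior quadromer: the position reading exactly that window
  # keeps its prediction
  i <- 20  # window i covers residues i-3 .. i
  set.seed(45)
  r2 <- r
  r2[17:20] <- sample(r[17:20])
  prot2 <- paste(r2, collapse = "")
  expect_equal(svr_spectrum(svr, prot)[i], svr_spectrum(svr, prot2)[i])
})

test_that("permutation augmentation preserves signals and counts", {
  pairs <- data.frame(kmer = c("GQLD", "AAAA", "KLMN"),
                      signal = c(0.1, -0.2, 0.5))
  expect_identical(augment_permute(pairs, 0), pairs)
  aug <- augment_permute(pairs, 5, seed = 7)
  expect_equal(nrow(aug), 3 * (1 + 5))
  # permuted k-mers keep the multiset and the signal of their source
  for (j in seq_len(nrow(aug))) {
    src <- pairs[match(aug$signal[j], pairs$signal), ]
    expect_equal(paste(sort(strsplit(aug$kmer[j], "")[[1]]), collapse = ""),
                 paste(sort(strsplit(src$kmer, "")[[1]]), collapse = ""))
  }
  # homopolymers only have one permutation
  expect_true(all(aug$kmer[aug$signal == -0.2] == "AAAA"))
  # deterministic under seed
  expect_identical(aug, augment_permute(pairs, 5, seed = 7))
})

test_that("RF recovers a known volume+hydrophilicity response on held-out data", {
  fn <- function(km) window_mean_volume(km) + 0.02 * window_mean_hydro(km)
  pairs <- labelled_pairs(random_protein(200, seed = 51), fn)
  rf <- train_rf(augment_permute(pairs, 5, seed = 3), n_trees = 100, seed = 3)
  held_out <- random_protein(80, seed = 52)
  pred <- rf_spectrum(rf, held_out)
  truth <- vapply(protein_windows(held_out, pad = TRUE), fn, numeric(1))
  expect_gt(cor(pred, truth), 0.8)
  # predictions bounded by the training signal range
  expect_true(all(pred <= max(pairs$signal) & pred >= min(pairs$signal)))
  # training twice with the same seed gives identical predictions
  rf2 <- train_rf(augment_permute(pairs, 5, seed = 3), n_trees = 100, seed = 3)
  expect_identical(pred, rf_spectrum(rf2, held_out))
  expect_error(train_rf(pairs[0, ]), "empty")
})

test_that("RF trained on MV labels reproduces the MV ordering", {
  pairs <- do.call(rbind, lapply(61:63, function(s)
    labelled_pairs(random_protein(150, seed = s), window_mean_volume)))
  rf <- train_rf(augment_permute(pairs, 5, seed = 5), seed = 5)
  held_out <- random_protein(100, seed = 62)
  expect_gt(cor(rf_spectrum(rf, held_out), mv_spectrum(held_out),
                method = "spearman"), 0.9)
})

test_that("augmented RF is statistically order-free within windows", {
  pairs <- labelled_pairs(random_protein(200, seed = 71), window_mean_volume)
  rf <- train_rf(augment_permute(pairs, 10, seed = 7), seed = 7)
  set.seed(72)
  aas <- aa_properties()$residue
  diffs <- replicate(100, {
    km <- paste(sample(aas, 4, replace = TRUE), collapse = "")
    perm <- paste(sample(strsplit(km, "")[[1]]), collapse = "")
    feats <- rbind(as.numeric(t(pair_feature(km))),
                   as.numeric(t(pair_feature(perm))))
    colnames(feats) <- rf$feature_names
    p <- predict(rf$fit, feats)
    p[1] - p[2]
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
  expect_lt(mean(abs(diffs)), 0.5 * sd(pairs$signal))
})

test_that("signed error profiles expose constructed biases", {
  prot <- random_protein(120, seed = 81)
  theo_raw <- vapply(protein_windows(prot, pad = TRUE), window_mean_hydro,
                     numeric(1))
  theo <- znormalize(theo_raw)
  # no bias: identical spectra give an all-zero profile
  se0 <- signed_error(theo, theo, prot)
  present <- !is.na(se0$profile$mean_error)
  expect_true(all(abs(se0$profile$mean_error[present]) < 1e-12))
  # constructed volume bias: error proportional to the volume profile
  emp <- znormalize(theo + 0.8 * znormalize(mv_spectrum(prot)))
  se <- signed_error(emp, theo, prot)
  expect_gt(se$volume_slope, 0)
  expect_lt(se$volume_p, 0.05)
  expect_error(signed_error(theo[-1], theo, prot), "length mismatch")
})

test_that("residues absent from the protein are reported missing, not zero", {
  prot <- paste(rep(c("G", "A", "L", "K"), 10), collapse = "")  # no W
  theo <- znormalize(mv_spectrum(prot))
  set.seed(82)
  emp <- znormalize(theo + rnorm(length(theo), 0, 0.1))
  se <- signed_error(emp, theo, prot)
  expect_true(is.na(se$profile$mean_error[se$profile$residue == "W"]))
  expect_equal(se$profile$n_windows[se$profile$residue == "W"], 0)
  expect_false(anyNA(se$profile$mean_error[se$profile$residue %in%
                                             c("G", "A", "L", "K")]))
})
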