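# R^2 scoring, database search, decoys and p-value calibration.

test_that("r2_score implements the coefficient of determination", {
  obs <- znormalize(c(3, 1, 4, 1, 5))
  expect_equal(r2_score(obs, obs), 1)
  # a constant prediction explains nothing under the mean baseline
  expect_equal(r2_score(obs, rep(0, 5)), 0)
  # hand-computed five-point case
  o <- c(-1.2649, -0.6325, 0, 0.6325, 1.2649)
  p <- c(o[1:4], 1.0)
  expect_equal(r2_score(o, p), r2_oracle(o, p), tolerance = 1e-12)
  expect_equal(r2_score(o, p), 1 - (1.2649 - 1)^2 / sum((o - mean(o))^2))
  expect_error(r2_score(1:4, 1:5), "length mismatch")
})

test_that("r2_score agrees with an independent oracle on random pairs", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    o <- rnorm(n)
    p <- rnorm(n)
    expect_equal(r2_score(o, p), r2_oracle(o, p), tolerance = 1e-10)
  }
})

test_that("decoys preserve length and residue composition", {
  prot <- random_protein(50, seed = 111)
  dec <- generate_decoys(prot, 40, seed = 5)
  expect_equal(nrow(dec), 40)
  sorted <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  expect_true(all(vapply(dec$sequence, sorted, character(1)) == sorted(prot)))
  # deterministic under seed
  expect_identical(dec, generate_decoys(prot, 40, seed = 5))
  # degenerate homopolymer
  expect_true(all(generate_decoys("AAAA", 5, seed = 1)$sequence == "AAAA"))
})

test_that("identification ranks by R^2 with documented tie-breaking", {
  prot <- random_protein(40, seed = 121)
  db <- rbind(data.frame(id = "true", sequence = prot),
              generate_decoys(prot, 30, seed = 2))
  sim <- simulate_blockade(prot, simulation_config(orientation_prob = 0),
                           seed = 9)
  res <- identify_protein(sim$spectrum, db, mv_model())
  expect_equal(nrow(res), 31)
  expect_equal(res$rank, 1:31)
  expect_false(is.unsorted(rev(res$r2)))
  expect_equal(res$protein_id[1], "true")
  # permutation invariance of database order
  set.seed(122)
  perm <- db[sample(nrow(db)), ]
  res2 <- identify_protein(sim$spectrum, perm, mv_model())
  expect_equal(res2, res)
  # single-candidate database
  one <- identify_protein(sim$spectrum, db[1, , drop = FALSE], mv_model())
  expect_equal(one$rank, 1L)
})

test_that("orientation handling finds the reversed translocation", {
  prot <- random_protein(45, seed = 131)
  db <- rbind(data.frame(id = "true", sequence = prot),
              generate_decoys(prot, 30, seed = 3))
  fwd <- simulate_blockade(prot, simulation_config(orientation_prob = 0),
                           seed = 13)$spectrum
  rev <- spec_of(rev(fwd$values), fwd$duration_ms)
  res_f <- identify_protein(fwd, db, mv_model(), both_orientations = TRUE)
  res_r <- identify_protein(rev, db, mv_model(), both_orientations = TRUE)
  expect_equal(res_f$protein_id[1], "true")
  expect_equal(res_r$protein_id[1], "true")
  expect_equal(res_f$orientation[1], "forward")
  expect_equal(res_r$orientation[1], "reverse")
})

test_that("candidates longer than the spectrum are skipped with a warning", {
  short <- spec_of(rnorm(20) + 2, 1)
  db <- data.frame(id = c("fits", "toolong"),
                   sequence = c(random_protein(10, seed = 1),
                                random_protein(200, seed = 2)))
  expect_warning(res <- identify_protein(short, db, mv_model()), "skipped")
  expect_equal(res$protein_id, "fits")
})

test_that("p-values use strictly-greater counting plus a pseudocount", {
  prot <- random_protein(40, seed = 141)
  dec <- generate_decoys(prot, 50, seed = 4)
  sim <- simulate_blockade(prot, simulation_config(orientation_prob = 0,
                                                   noise_sigma = 0),
                           seed = 14)
  pv <- pvalue(sim$spectrum, prot, dec, mv_model())
  # a noiseless self-match outranks every decoy
  expect_equal(pv$p_value, 0)
  expect_equal(pv$p_value_pseudocount, 1 / 51)
  expect_equal(pv$n_decoys, 50)
  expect_error(pvalue(sim$spectrum, prot, dec[0, ], mv_model()), "empty")
})

test_that("p-values are invariant under positive affine spectrum transforms", {
  prot <- random_protein(35, seed = 151)
  dec <- generate_decoys(prot, 60, seed = 6)
  sim <- simulate_blockade(prot, seed = 15)
  v <- sim$spectrum$values
  pv1 <- pvalue(spec_of(v, 5), prot, dec, mv_model())
  pv2 <- pvalue(spec_of(3 * v + 0.7, 5), prot, dec, mv_model())
  expect_equal(pv1$p_value, pv2$p_value)
  expect_equal(pv1$r2_true, pv2$r2_true, tolerance = 1e-9)
})

test_that("null p-values are roughly uniform at desk scale", {
  # spectra from random proteins scored against exchangeable shuffles
  set.seed(161)
  pvals <- replicate(60, {
    a <- random_protein(30, seed = sample.int(1e6, 1))
    sim <- simulate_blockade(a, seed = sample.int(1e6, 1))
    residues <- strsplit(a, "")[[1]]
    b <- paste(sample(residues), collapse = "")
    dec <- generate_decoys(b, 99, seed = sample.int(1e6, 1))
    pvalue(sim$spectrum, b, dec, mv_model())$p_value
  })
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("FASTA databases round-trip and drive identification", {
  db <- rbind(data.frame(id = "p1", sequence = random_protein(30, seed = 1)),
              data.frame(id = "p2", sequence = random_protein(30, seed = 2)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_db(db, path)
  back <- read_fasta_db(path)
  expect_equal(back, db)
})
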