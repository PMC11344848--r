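# The three comparison methods and cross-family averaging.

test_that("whole-sequence similarity is 1 for identical, symmetric", {
  p <- fp_params(signature_length = 256, seed = 4)
  expect_equal(full_similarity("CGGSGGC", "CGGSGGC", p), 1)
  ab <- full_similarity("CGGSGGC", "CGSGGSGC", p)
  ba <- full_similarity("CGSGGSGC", "CGGSGGC", p)
  expect_equal(ab, ba)
  expect_true(ab >= 0 && ab <= 1)
})

test_that("P2 vs P3 estimate agrees with the exact-Jaccard oracle", {
  p <- fp_params(signature_length = 2048, seed = 4)
  est <- full_similarity("CGGSGGC", "CGSGGSGC", p)
  exact <- full_similarity("CGGSGGC", "CGSGGSGC", p, exact = TRUE)
  expect_lt(abs(est - exact), 0.05)
})

test_that("positional profiles align residues and short-circuit identity", {
  p <- fp_params(signature_length = 256, seed = 4)
  a <- "CPANAAAPAAAC"
  b <- "CGHNKLMPQRSC"
  prof <- positional_similarity(a, b, p)
  expect_equal(nrow(prof), 12L)
  expect_named(prof, c("position", "residue_a", "residue_b", "similarity"))
  same <- prof$residue_a == prof$residue_b
  expect_identical(prof$similarity[same], rep(1, sum(same)))
  expect_true(all(prof$similarity >= 0 & prof$similarity <= 1))

  self <- positional_similarity(a, a, p)
  expect_identical(self$similarity, rep(1, 12L))

  expect_error(positional_similarity("AAA", "AAAA", p), "equal lengths")
})

test_that("positional G vs A matches the exact residue-set Jaccard", {
  p <- fp_params(signature_length = 2048, seed = 4)
  est <- positional_similarity("G", "A", p)$similarity
  exact <- positional_similarity("G", "A", p, exact = TRUE)$similarity
  expect_lt(abs(est - exact), 0.05)
  expect_lt(exact, 1)
})

test_that("tf-idf cosine reproduces the hand-computed toy corpus", {
  mat <- tfidf_cosine(c(a = "AAG", b = "AGG", c = "CCC"))
  # oracle: smoothed-idf weighted vectors, L2-normalized, dotted
  expect_equal(unclass(mat)[, ],
               matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
               tolerance = 1e-12, ignore_attr = "class")
  expect_equal(diag(unclass(mat)), c(a = 1, b = 1, c = 1))

  ident <- tfidf_cosine(c(x = "AAG", y = "AAG"))
  expect_equal(ident["x", "y"], 1)

  disjoint <- tfidf_cosine(c(x = "AAA", y = "GGG"))
  expect_equal(disjoint["x", "y"], 0)

  expect_error(tfidf_cosine(character(0)), "empty panel")
})

test_that("pairwise matrices are symmetric, unit-diagonal, reproducible", {
  p <- fp_params(signature_length = 256, seed = 4)
  panel <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    sequence = c("CPANAAAPAAAC", "CGHNKLMPQRSC", "CPANAAAPAAAC")
  )
  for (m in c("full_map4", "positional_mean", "tfidf_cosine")) {
    mat <- pairwise_matrix(panel, m, params = p)
    expect_true(isSymmetric(unclass(mat)))
    expect_equal(diag(unclass(mat)), c(s1 = 1, s2 = 1, s3 = 1))
    expect_true(all(mat >= 0 & mat <= 1))
  }
  # duplicated sequence: similarity exactly 1
  mat <- pairwise_matrix(panel, "full_map4", params = p)
  expect_equal(mat["s1", "s3"], 1)
  # entries match one-by-one calls
  expect_equal(mat["s1", "s2"],
               full_similarity(panel$sequence[1], panel$sequence[2], p))

  expect_error(pairwise_matrix(panel[c(1, 1), ], "full_map4", p),
               "duplicate")
  uneq <- tibble::tibble(id = c("a", "b"), sequence = c("AG", "AGG"))
  expect_error(pairwise_matrix(uneq, "positional_mean", p), "equal-length")
})

test_that("tidy/glance on similarity matrices cover off-diagonal pairs", {
  mat <- tfidf_cosine(c(a = "AAG", b = "AGG", c = "CCC"))
  td <- tidy(mat)
  expect_equal(nrow(td), 3L)
  expect_equal(sort(td$similarity), c(0, 0, 0.8), tolerance = 1e-12)
  g <- glance(mat)
  expect_equal(g$n_peptides, 3L)
  expect_equal(g$mean_similarity, mean(c(0.8, 0, 0)))
})

test_that("cross-family averages exclude self and handle singletons", {
  m <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mat <- pepsim:::new_similarity_matrix(m, "full_map4", NULL)
  cmp <- cross_family_averages(mat, "a", "b")
  expect_equal(cmp$cross_mean, c(0.4, 0.4))
  expect_true(all(is.na(cmp$within_mean)))  # singleton groups: undefined

  # 4x4: diagonal never contributes
  m4 <- diag(1, 4)
  m4[upper.tri(m4)] <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  m4 <- m4 + t(m4) - diag(diag(m4))
  dimnames(m4) <- list(letters[1:4], letters[1:4])
  mat4 <- pepsim:::new_similarity_matrix(m4, "full_map4", NULL)
  cmp4 <- cross_family_averages(mat4, c("a", "b"), c("c", "d"))
  expect_equal(cmp4$within_mean[cmp4$id == "a"], m4["a", "b"])
  expect_equal(cmp4$cross_mean[cmp4$id == "a"], mean(m4["a", c("c", "d")]))
  expect_equal(cmp4$within_mean[cmp4$id == "c"], m4["c", "d"])

  expect_error(cross_family_averages(mat4, c("a", "b"), c("b", "c")),
               "disjoint")
  expect_error(cross_family_averages(mat4, "a", "zz"), "not in matrix")
})

test_that("groups of identical sequences give cross mean 1", {
  p <- fp_params(signature_length = 128, seed = 4)
  panel <- tibble::tibble(id = c("a1", "a2", "b1"),
                          sequence = rep("CGGSGGC", 3))
  mat <- pairwise_matrix(panel, "full_map4", params = p)
  cmp <- cross_family_averages(mat, c("a1", "a2"), "b1")
  expect_equal(cmp$cross_mean, rep(1, 3))
})
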