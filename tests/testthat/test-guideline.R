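test_that("guideline construction validates ranges and defaults the reference", {
  g <- guideline_spec(c("dairy", "salt"), low = c(300, 0), high = c(500, 5))
  expect_equal(g$reference, c(400, 2.5))

  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group,low,high", "dairy,300,500", "salt,0,5"), tf)
  g2 <- load_guideline(tf)
  expect_equal(g2$reference, c(400, 2.5))

  writeLines(c("group,low", "dairy,300"), tf)
  expect_error(load_guideline(tf), "missing column")
  expect_error(guideline_spec(c("a", "a"), c(0, 0), c(1, 1)), "duplicated")
  expect_error(guideline_spec("a", 5, 2), "row\\(s\\) 1")
  expect_error(guideline_spec("a", -1, 2), "row")
  expect_error(guideline_spec("a", 0, 2, reference = 3), "outside")
})

test_that("ratio normalization maps the reference to 1 and matches elementwise division", {
  g <- toy_guideline()
  expect_equal(normalize_intake(g$reference, g)$x[1, ],
               rep(1, 10), ignore_attr = TRUE)
  v <- g$reference; v[1] <- 2 * g$reference[1]
  expect_equal(normalize_intake(v, g)$x[1, ], c(2, rep(1, 9)),
               ignore_attr = TRUE)
  set.seed(42)
  for (k in 1:20) {
    v <- runif(10, 0, 500)
    got <- normalize_intake(v, g)$x[1, ]
    want <- vapply(1:10, function(i) v[i] / g$reference[i], 0)
    expect_equal(unname(got), want, tolerance = 1e-15)
  }
  g0 <- guideline_spec("a", 0, 5, reference = 0)
  expect_error(normalize_intake(3, g0), "positive reference")
})

test_that("dnas equals the brute-force distance oracle on random vectors", {
  g <- toy_guideline()
  expect_equal(compute_dnas(g$reference, g), 0)
  v <- g$reference; v[3] <- 2 * g$reference[3]
  expect_equal(compute_dnas(v, g, metric = "euclidean"), 1)
  expect_equal(compute_dnas(v, g, metric = "manhattan"), 1)
  set.seed(7)
  for (k in 1:20) {
    v <- runif(10, 0, 600)
    xn <- v / g$reference
    expect_equal(compute_dnas(v, g, "euclidean"),
                 oracle_distance(xn, rep(1, 10), "euclidean"),
                 tolerance = 1e-12)
    expect_equal(compute_dnas(v, g, "manhattan"),
                 oracle_distance(xn, rep(1, 10), "manhattan"),
                 tolerance = 1e-12)
  }
})

test_that("euclidean score satisfies the metric axioms on random triples", {
  # work in grams mode so arbitrary points (not just the reference) can be
  # compared through the underlying distance
  dist_to_ref <- function(v, ref) {
    g <- guideline_spec(paste0("g", 1:10), low = rep(0, 10),
                        high = rep(1000, 10), reference = ref)
    compute_dnas(v, g, mode = "grams")
  }
  set.seed(11)
  for (k in 1:25) {
    a <- runif(10, 0, 100); b <- runif(10, 0, 100); c <- runif(10, 0, 100)
    dab <- dist_to_ref(a, b)
    expect_gte(dab, 0)
    expect_equal(dist_to_ref(a, a), 0)
    expect_equal(dab, dist_to_ref(b, a))                     # symmetry
    expect_lte(dist_to_ref(a, c), dab + dist_to_ref(b, c) + 1e-12)
  }
})

test_that("ratio mode is scale invariant and the score is coordinatewise monotone", {
  g <- toy_guideline()
  set.seed(3)
  for (k in 1:10) {
    v <- runif(10, 1, 500)
    s0 <- compute_dnas(v, g)
    # scale group 1 grams and its reference by the same constant
    const <- runif(1, 0.1, 10)
    g2 <- g
    g2$low[1] <- g$low[1] * const; g2$high[1] <- g$high[1] * const
    g2$reference[1] <- g$reference[1] * const
    v2 <- v; v2[1] <- v[1] * const
    expect_equal(compute_dnas(v2, g2), s0, tolerance = 1e-12)
    # pushing one coordinate further from its reference never lowers it
    v3 <- v
    v3[5] <- g$reference[5] + 2 * (v[5] - g$reference[5])
    expect_gte(compute_dnas(v3, g), s0 - 1e-12)
    # norm inequality
    expect_lte(compute_dnas(v, g, "euclidean"),
               compute_dnas(v, g, "manhattan") + 1e-12)
  }
})

test_that("score_panel preserves cardinality, orders output, rejects duplicates", {
  g <- toy_guideline()
  p <- random_panel(3, c(2004, 2006, 2009, 2011), g, seed = 5)
  d <- score_panel(p, g)
  expect_equal(nrow(d), 12)
  expect_equal(d$subject_id, sort(d$subject_id))
  expect_false(is.unsorted(d$round[d$subject_id == d$subject_id[1]]))

  expect_equal(nrow(score_panel(p[0, ], g)), 0)

  pref <- p
  pref[, g$group] <- rep(g$reference, each = nrow(p))
  expect_equal(score_panel(pref, g)$score, rep(0, 12))

  pdup <- rbind(p, p[1, ])
  expect_error(score_panel(pdup, g), "duplicated")
})

test_that("zscore mode standardizes by the fitted sample statistics", {
  g <- toy_guideline()
  p <- random_panel(5, 1:3, g, seed = 9)
  st <- intake_stats(p, g)
  nm <- normalize_intake(as.matrix(p[, g$group]), g, mode = "zscore",
                         stats = st)
  expect_equal(colMeans(nm$x), rep(0, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(nm$x, 2, sd), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(normalize_intake(g$reference, g, mode = "zscore"), "stats")
})

test_that("the shipped default guideline loads and has ten unique groups", {
  g <- default_guideline()
  expect_s3_class(g, "guideline_spec")
  expect_equal(nrow(g), 10)
  expect_false(anyDuplicated(g$group) > 0)
  expect_true(all(g$reference > 0))
})
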