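test_that("share_matrix validates row sums, range and labels", {
  m <- share_matrix(rbind(c(0.5, 0.5), c(0.2, 0.8)),
                    row_labels = c("2029", "2030"),
                    col_labels = c("a", "b"))
  expect_s3_class(m, "share_matrix")
  expect_error(share_matrix(rbind(c(0.5, 0.3))), "sum to 1")
  expect_error(share_matrix(rbind(c(1.5, -0.5))), "\\[0, 1\\]")
  expect_error(share_matrix(rbind(c(0.4, 0.4), c(0.5, 0.5)))
               , "'1'")  # offending row named
})

test_that("compose_form_shares multiplies and preserves stochasticity", {
  # identity case: one year, one category
  E1 <- share_matrix(matrix(1), row_labels = "2030", col_labels = "cat")
  F1 <- share_matrix(matrix(c(0.33, 0.33, 0.34), 1),
                     row_labels = "cat", col_labels = c("pG", "GO", "rGO"))
  expect_equal(unclass(compose_form_shares(E1, F1))[1, ],
               c(pG = 0.33, GO = 0.33, rGO = 0.34))

  # hand multiplication
  E <- share_matrix(matrix(c(0.5, 0.5), 1), row_labels = "y",
                    col_labels = c("c1", "c2"))
  F <- share_matrix(rbind(c(1, 0, 0), c(0, 1, 0)),
                    row_labels = c("c1", "c2"),
                    col_labels = c("pG", "GO", "rGO"))
  expect_equal(unclass(compose_form_shares(E, F))[1, ],
               c(pG = 0.5, GO = 0.5, rGO = 0))

  # label mismatch is a structured error naming the offender
  Fbad <- share_matrix(rbind(c(1, 0, 0), c(0, 1, 0)),
                       row_labels = c("c1", "cX"),
                       col_labels = c("pG", "GO", "rGO"))
  expect_error(compose_form_shares(E, Fbad), "cX")

  # property: row-stochasticity preserved for random conforming inputs
  set.seed(42)
  for (i in 1:10) {
    Er <- random_share_matrix(5, 4, col_labels = paste0("k", 1:4))
    Fr <- random_share_matrix(4, 3, row_labels = paste0("k", 1:4))
    G <- compose_form_shares(Er, Fr)
    expect_true(all(abs(rowSums(G) - 1) < 1e-9))
  }
})

test_that("reallocate_categories renormalises by the form share", {
  E <- share_matrix(matrix(c(0.6, 0.4), 1), row_labels = "y",
                    col_labels = c("c1", "c2"))
  F <- share_matrix(rbind(c(0.5, 0.5), c(1.0, 0.0)),
                    row_labels = c("c1", "c2"), col_labels = c("z", "w"))
  out <- reallocate_categories(E, F, "z")
  expect_equal(unclass(out)[1, ], c(c1 = 0.3 / 0.7, c2 = 0.4 / 0.7),
               tolerance = 1e-12)
  expect_equal(sum(out), 1)

  # single source category
  F1 <- share_matrix(matrix(1), row_labels = "c", col_labels = "z")
  E1 <- share_matrix(matrix(rep(1, 3)), row_labels = c("1", "2", "3"),
                     col_labels = "c")
  expect_true(all(unclass(reallocate_categories(E1, F1, "z")) == 1))

  # a form absent from the market raises, naming year and form
  Fz <- share_matrix(rbind(c(1, 0), c(1, 0)),
                     row_labels = c("c1", "c2"), col_labels = c("z", "dead"))
  expect_error(reallocate_categories(E, Fz, "dead"), "dead")
})

test_that("allocate_form_production splits and conserves sample-wise", {
  G <- share_matrix(matrix(c(0.5, 0.25, 0.25), 1), row_labels = "2030",
                    col_labels = c("pG", "GO", "rGO"))
  P <- matrix(100, 1, 1, dimnames = list("2030", NULL))
  expect_equal(unname(allocate_form_production(P, G, "pG")[1, 1]), 50)
  expect_equal(unname(allocate_form_production(P, G, "GO")[1, 1]), 25)
  expect_equal(unname(allocate_form_production(0 * P, G, "rGO")[1, 1]), 0)
  expect_error(allocate_form_production(
    matrix(1, 1, 1, dimnames = list("1999", NULL)), G, "pG"), "1999")

  # conservation property over random samples
  set.seed(7)
  Gr <- random_share_matrix(4, 3, row_labels = as.character(2027:2030),
                            col_labels = c("pG", "GO", "rGO"))
  Pr <- matrix(rlnorm(4 * 20), 4, 20,
               dimnames = list(as.character(2027:2030), NULL))
  total <- Reduce(`+`, lapply(c("pG", "GO", "rGO"), function(z) {
    allocate_form_production(Pr, Gr, z)
  }))
  expect_equal(total, Pr, tolerance = 1e-9)
})

test_that("combine_market_matrices weights market fractions into rows", {
  # symmetric two-form case over one effective application
  A <- c(f1 = 0.5, f2 = 0.5)
  B <- matrix(c(1, 1), 2, 1, dimnames = list(c("f1", "f2"), "app"))
  expect_equal(unclass(combine_market_matrices(A, B))["app", ],
               c(f1 = 0.5, f2 = 0.5))

  # hand arithmetic
  A2 <- c(f1 = 0.62, f2 = 0.38)
  B2 <- rbind(f1 = c(0.8, 0.2), f2 = c(0.2, 0.8))
  colnames(B2) <- c("app1", "app2")
  D <- combine_market_matrices(A2, B2)
  expect_equal(unclass(D)["app1", ],
               c(f1 = 0.62 * 0.8, f2 = 0.38 * 0.2) / 0.572,
               tolerance = 1e-12)
  expect_equal(unname(round(unclass(D)["app1", ], 4)), c(0.8671, 0.1329))

  # an application untouched by every form is an error
  B3 <- rbind(f1 = c(1, 0), f2 = c(1, 0))
  colnames(B3) <- c("app1", "app2")
  expect_error(combine_market_matrices(A2, B3), "app2")
})

test_that("apply_split_rules covers the four rule families", {
  expect_equal(apply_split_rules(list(rule = "go_halving",
                                      shares = c(pG = 0, GO = 1))),
               c(pG = 0, GO = 0.5, rGO = 0.5))
  eq <- apply_split_rules(list(rule = "equal_split"))
  expect_equal(unname(eq), rep(1 / 3, 3))
  mix <- apply_split_rules(list(
    rule = "mixture", weights = c(0.9, 0.1),
    components = list(c(pG = 1, GO = 0, rGO = 0), c(pG = 0, GO = 1, rGO = 0))))
  expect_equal(mix, c(pG = 0.9, GO = 0.1, rGO = 0))
  expect_error(apply_split_rules(list(rule = "banana")), "unknown split rule")
  expect_error(apply_split_rules(list(
    rule = "mixture", weights = c(0.5, 0.4),
    components = list(c(pG = 1, GO = 0, rGO = 0), c(pG = 0, GO = 1, rGO = 0)))),
    "sum to 1")
  # always sums to 1
  set.seed(1)
  for (i in 1:5) {
    sh <- runif(2); sh <- sh / sum(sh)
    out <- apply_split_rules(list(rule = "go_halving",
                                  shares = c(pG = sh[1], GO = sh[2])))
    expect_equal(sum(out), 1, tolerance = 1e-9)
  }
})

test_that("shipped split table is exact and rounds to the published percents", {
  F <- gbm_form_splits()
  expect_true(all(abs(rowSums(F) - 1) < 1e-12))   # exact fractions, not 0.99
  pct <- format_share_percent(F)
  expect_equal(unname(pct["construction", ]), c(0L, 50L, 50L))
  expect_equal(unname(pct["drilling_fluid", ]), c(33L, 33L, 33L))
  expect_equal(unname(pct["aerospace_aviation", ]), c(81L, 10L, 10L))
  expect_equal(unname(pct["batteries", ]), c(57L, 22L, 22L))
  expect_equal(unname(pct["automotive", ]), c(77L, 12L, 12L))
  expect_equal(unname(pct["research_development", ]), c(71L, 17L, 12L))
  expect_equal(unname(pct["electronics", ]), c(100L, 0L, 0L))
})

test_that("share matrices round-trip through CSV with validation", {
  m <- random_share_matrix(3, 4, row_labels = as.character(2028:2030))
  path <- withr::local_tempfile(fileext = ".csv")
  write_share_matrix(m, path)
  back <- read_share_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)

  # corrupt a row and expect the validator to name it
  bad <- unclass(m); bad[2, ] <- bad[2, ] * 0.8
  df <- data.frame(label = rownames(bad), bad, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_share_matrix(path), "2029")
})
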