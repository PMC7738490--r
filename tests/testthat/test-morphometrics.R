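test_that("q_ratio rounds half away from zero to two decimals", {
  expect_equal(q_ratio(7.2, 5.1), 1.41)
  expect_equal(q_ratio(5.6, 2.87), 1.95)
  # 6.1 / 4 = 1.525: half-up gives 1.53 (banker's rounding would give 1.52)
  expect_equal(q_ratio(6.1, 4), 1.53)
  expect_equal(q_ratio(c(7.2, 6.1), c(5.1, 4)), c(1.41, 1.53))
  expect_error(q_ratio(-1, 2), "positive")
  expect_true(is.na(q_ratio(NA, 2)))
})

test_that("specimen_summary averages measurements and derives Q", {
  s <- specimen_summary(basidia_L = c(29, 30, 31), basidia_W = c(5, 5.2),
                        spore_L = c(7, 7.4), spore_W = c(5.0, 5.2))
  expect_equal(unname(s), c(30, 5.1, 7.2, 5.1, q_ratio(7.2, 5.1)))
  # missing basidia leave basidia columns NA but keep spores
  s2 <- specimen_summary(spore_L = c(6, 6.2), spore_W = c(4, 4))
  expect_true(all(is.na(s2[c("basidia_L", "basidia_W")])))
  expect_equal(unname(s2["spore_Q"]), q_ratio(6.1, 4))
  expect_error(specimen_summary(), "no measurements")
})

test_that("one_way_anova matches hand values and the squared t", {
  # hand example: a = (0, 2), b = (4, 6): F = 8 on (1, 2) df
  r <- one_way_anova(c(0, 2), c(4, 6))
  expect_equal(r$f, 8)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 2L)
  expect_equal(r$p_value, 1 - stats::pf(8, 1, 2), tolerance = 1e-12)
  # F equals the squared pooled-variance t on random datasets
  set.seed(17)
  for (i in 1:200) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- rnorm(na, sd = runif(1, .5, 2)); b <- rnorm(nb, mean = runif(1))
    r <- one_way_anova(a, b)
    expect_equal(r$f, oracle_f_from_t(a, b), tolerance = 1e-10)
    expect_equal(r$df_within, na + nb - 2L)
  }
  # affine invariance: F(kx + c) = F(x)
  a <- c(1, 2, 3, 5); b <- c(4, 6, 7)
  expect_equal(one_way_anova(3 * a - 10, 3 * b - 10)$f,
               one_way_anova(a, b)$f, tolerance = 1e-10)
  # NA handling and degenerate cases
  expect_equal(one_way_anova(c(a, NA), b)$f, one_way_anova(a, b)$f)
  expect_error(one_way_anova(c(1, NA), b), "at least 2")
  expect_error(one_way_anova(c(1, 1), c(1, 1)), "undefined")
  dg <- one_way_anova(c(1, 1), c(2, 2))
  expect_true(dg$degenerate && is.infinite(dg$f) && dg$p_value == 0)
})

test_that("the packaged specimen table is internally consistent", {
  fx <- table1_fixture()
  expect_equal(dim(fx$traits), c(38L, 5L))
  expect_identical(colnames(fx$traits),
                   c("basidia_L", "basidia_W", "spore_L", "spore_W",
                     "spore_Q"))
  expect_identical(rownames(fx$traits), fx$info$specimen)
  # the two holotypes carry their published measurements
  expect_equal(unname(fx$traits["K 56442 (Holotype)", ]),
               c(29.8, 5.1, 7.2, 5.1, 1.41))
  expect_equal(unname(fx$traits["MA-Fungi 90397 (Holotype)", ]),
               c(24.5, 4.75, 5.6, 2.87, 1.95))
  # one specimen has no measurements at all, one lacks only basidia
  expect_true(all(is.na(fx$traits["MA-Fungi 91820", ])))
  expect_true(all(is.na(fx$traits["MA-Fungi 91818", c("basidia_L",
                                                      "basidia_W")])))
  expect_false(anyNA(fx$traits["MA-Fungi 91818", c("spore_L", "spore_W",
                                                   "spore_Q")]))
  # printed Q agrees with the rounded length/width ratio within one unit in
  # the last printed decimal, on every row with complete spore data
  ok <- stats::complete.cases(fx$traits[, c("spore_L", "spore_W",
                                            "spore_Q")])
  qq <- q_ratio(fx$traits[ok, "spore_L"], fx$traits[ok, "spore_W"])
  expect_true(all(abs(qq - fx$traits[ok, "spore_Q"]) <= 0.011))
})

test_that("the two named clades differ significantly in every trait", {
  fx <- table1_fixture()
  grp <- stats::setNames(fx$info$clade, fx$info$specimen)
  grp <- grp[!is.na(grp)]
  rep <- clade_morphology_report(fx$traits, grp)
  expect_identical(rep$clades, c("Australia", "Patagonia"))
  for (tr in names(rep$anova))
    expect_lt(rep$anova[[tr]]$p_value, 0.01)
  # Australian spores are longer and wider; Patagonian ones more elongate
  d <- rep$descriptives
  m <- function(tr, cl) d$mean[d$trait == tr & d$clade == cl]
  expect_gt(m("spore_L", "Australia"), m("spore_L", "Patagonia"))
  expect_gt(m("spore_W", "Australia"), m("spore_W", "Patagonia"))
  expect_lt(m("spore_Q", "Australia"), m("spore_Q", "Patagonia"))
})

test_that("anova_subset_search finds a planted exact subset", {
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("s", 1:10), c("u", "v")))
  A <- c("s1", "s2", "s3"); B <- c("s6", "s7", "s8", "s9")
  target <- vapply(c("u", "v"), function(tr)
    round_half_up(one_way_anova(X[A, tr], X[B, tr])$f, 2L), numeric(1))
  res <- anova_subset_search(X, paste0("s", 1:5), paste0("s", 6:10),
                             3, 4, target)
  expect_true(res$exact)
  f <- vapply(c("u", "v"), function(tr)
    one_way_anova(X[res$subset_a, tr], X[res$subset_b, tr])$f, numeric(1))
  expect_equal(round_half_up(f, 2L), target)
  # unreachable target falls back to the best subset, fully enumerated
  res2 <- anova_subset_search(X, paste0("s", 1:4), paste0("s", 6:9),
                              3, 3, c(u = 1000, v = 1000))
  expect_false(res2$exact)
  expect_equal(res2$n_evaluated, choose(4, 3)^2)
  expect_equal(res2$deviation, res2$f - c(u = 1000, v = 1000))
})
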