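test_that("the identity family is deterministic and exact", {
  s <- generate_sample(sim_spec("identity", m_a = 10, fc_true = 3,
                                n_a = 5, n_b = 5))
  expect_identical(s$a, rep(10, 5))
  expect_identical(s$b, rep(30, 5))
  expect_identical(s$fc_true, 3)
  expect_false(s$contains_nonpositive)
})

test_that("every family regenerates bit-identically from its seed", {
  fams <- c("identity", "uniform", "normal", "lognormal",
            "mixed_normal_lognormal", "mixed_lognormal_normal", "mixed")
  for (f in fams) {
    spec <- sim_spec(f, m_a = 50, fc_true = 2, s_a = 1, s_b = 1,
                     n_a = 30, n_b = 40, seed = 77)
    s1 <- generate_sample(spec)
    s2 <- generate_sample(spec)
    expect_identical(s1$a, s2$a, label = f)
    expect_identical(s1$b, s2$b, label = f)
    expect_length(s1$a, 30)
    expect_length(s1$b, 40)
  }
})

test_that("the log-normal family targets the median ratio, not the mean ratio", {
  n <- 1e5
  s <- generate_sample(sim_spec("lognormal", m_a = 35, fc_true = 2,
                                s_a = 1, s_b = 1, n_a = n, n_b = n,
                                seed = 13))
  med_ratio <- median(s$b) / median(s$a)
  # asymptotic SE of a log-normal sample median on the log scale
  se <- sqrt(2) * 1.2533 * 1 / sqrt(n)
  expect_lt(abs(log(med_ratio) - log(2)), 3 * se)
  # the arithmetic-mean ratio has the same target only because s_a == s_b
  expect_equal(mean(s$b) / mean(s$a), 2, tolerance = 0.1)
})

test_that("uniform groups have expectation m/2 on each side", {
  s <- generate_sample(sim_spec("uniform", m_a = 100, fc_true = 1,
                                n_a = 1e5, n_b = 1e5, seed = 14))
  se <- 100 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(s$a) - 50), 3 * se)
  expect_lt(abs(mean(s$b) - 50), 3 * se)
})

test_that("mixed families cross the group distributions as specified", {
  s <- generate_sample(sim_spec("mixed_normal_lognormal", m_a = 100,
                                fc_true = 2, s_a = 10, s_b = 1,
                                n_a = 5000, n_b = 5000, seed = 15))
  # a is normal around 100; b is log-normal with median 200
  expect_equal(mean(s$a), 100, tolerance = 1)
  expect_equal(sd(s$a), 10, tolerance = 1)
  expect_equal(median(s$b), 200, tolerance = 12)
  expect_gt(mean(s$b), median(s$b))  # log-normal right skew
})

test_that("non-positive normal draws are flagged, not truncated", {
  s <- generate_sample(sim_spec("normal", m_a = 5, fc_true = 1,
                                s_a = 10, s_b = 10, n_a = 200, n_b = 200,
                                seed = 16))
  expect_true(s$contains_nonpositive)
  expect_true(any(s$a <= 0) || any(s$b <= 0))
  expect_error(fold_change(s), "positive")
})

test_that("the sweep grid has the stated cardinality and bookkeeping", {
  sw <- generate_sweep(n = 10, seed = 17)
  expect_equal(nrow(sw$grid), 20 * 6 * 2)
  expect_length(sw$samples, 240)
  cell <- sw$grid[sw$grid$fc_true == 6 & sw$grid$s_ratio == 8 &
                  sw$grid$s_a == 1, ]
  expect_equal(cell$s_b, 8)
  null_cell <- which(sw$grid$fc_true == 1 & sw$grid$s_ratio == 1)
  expect_error(generate_sweep(fc_grid = c(-1, 2), n = 5), "positive")
  expect_error(generate_sweep(fc_grid = numeric(0), n = 5), "non-empty")
  # reproducibility of the whole collection
  sw2 <- generate_sweep(n = 10, seed = 17)
  expect_identical(lapply(sw$samples, `[[`, "a"),
                   lapply(sw2$samples, `[[`, "a"))
})

test_that("a null sweep cell draws both groups from the same distribution", {
  sw <- generate_sweep(fc_grid = 1, s_ratio_grid = 1, s_a_levels = 0.1,
                       n = 5000, seed = 18)
  s <- sw$samples[[1]]
  expect_gt(ks.test(s$a, s$b)$p.value, 0.01)
})

test_that("panel draws respect the parameter ranges", {
  p <- generate_panel(panel_spec(d = 99, family = "normal", seed = 19))
  expect_equal(nrow(p$meta), 99)
  expect_true(all(p$meta$m >= 500 & p$meta$m <= 600))
  expect_true(all(p$meta$s_a >= 20 & p$meta$s_a <= 200))
  expect_true(all(p$meta$s_b >= 20 & p$meta$s_b <= 200))
  expect_true(all(p$meta$fc_true >= 1/3 & p$meta$fc_true <= 3))

  pl <- generate_panel(panel_spec(d = 20, family = "lognormal", seed = 20))
  expect_true(all(pl$meta$m >= 30 & pl$meta$m <= 40))
  expect_true(all(pl$meta$s_a >= 1 & pl$meta$s_a <= 5))

  p1 <- generate_panel(panel_spec(d = 1, ratio_range = c(1, 1), seed = 21))
  expect_identical(p1$meta$fc_true, 1)

  pm <- generate_panel(panel_spec(d = 50, family = "mixed", seed = 22))
  expect_setequal(unique(pm$meta$family), c("normal", "lognormal"))
})

test_that("panels are reproducible and convert to labelled matrices", {
  spec <- panel_spec(d = 7, family = "lognormal", n_a = 4, n_b = 6, seed = 23)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(as.matrix(p1), as.matrix(p2))
  m <- as.matrix(p1)
  expect_equal(dim(m), c(7L, 10L))
  expect_identical(rownames(m), p1$meta$variable_id)
  lab <- panel_labels(p1)
  expect_identical(sum(lab == "reference"), 4L)
  expect_identical(sum(lab == "treatment"), 6L)
  expect_identical(names(lab), colnames(m))
  # matrix rows hold a then b
  expect_identical(unname(m[3, lab == "reference"]), p1$samples[[3]]$a)
})

test_that("global matrix permutation conserves the value multiset", {
  set.seed(24)
  m <- matrix(rlnorm(60, 3, 1), nrow = 6,
              dimnames = list(paste0("v", 1:6), paste0("s", 1:10)))
  pm <- permute_matrix(m, seed = 25)
  expect_identical(dim(pm), dim(m))
  expect_identical(dimnames(pm), dimnames(m))
  expect_identical(sort(as.vector(pm)), sort(as.vector(m)))
  expect_false(identical(pm, m))
  expect_identical(permute_matrix(m, seed = 25), pm)
  # constant matrix is a fixed point
  cm <- matrix(7, 3, 3)
  expect_identical(permute_matrix(cm, seed = 1), cm)
  expect_error(permute_matrix(matrix(numeric(0), 0, 0)), "non-empty")
  # 2x2 exhaustive: always one of the arrangements of the same 4 values
  m2 <- matrix(1:4 * 1.0, 2, 2)
  for (sd_ in 1:10) {
    p2 <- permute_matrix(m2, seed = sd_)
    expect_identical(sort(as.vector(p2)), as.vector(m2))
  }
})

test_that("spec validation rejects impossible parameters", {
  expect_error(sim_spec("lognormal", fc_true = -1), "fc_true")
  expect_error(sim_spec("lognormal", m_a = 0), "m_a")
  expect_error(sim_spec("normal", n_a = 0), "n_a")
  expect_error(panel_spec(d = 0), "d >= 1")
  expect_error(panel_spec(family = "poisson"), "family")
  expect_error(panel_spec(family = rep("normal", 3), d = 2), "length")
})
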