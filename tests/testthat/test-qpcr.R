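# Reference-gene stability statistics, efficiency-corrected expression
# ratios and growth-rate estimation, checked against hand-computed values.

make_cq <- function(mat, roles = NULL, conditions = NULL, efficiency = NULL) {
  cq_table(mat,
           gene_info = data.frame(gene = rownames(mat),
                                  role = roles %||% rep("candidate_RG", nrow(mat))),
           sample_info = data.frame(sample = colnames(mat),
                                    condition = conditions %||% rep("control", ncol(mat))),
           efficiency = efficiency)
}

test_that("relative quantities follow Q = E^(minCq - Cq)", {
  m <- rbind(g1 = c(20, 21, 23), g2 = c(30, 32, 30.5))
  colnames(m) <- paste0("s", 1:3)
  q <- relative_quantities(make_cq(m))
  expect_equal(q["g1", ], c(s1 = 1, s2 = 0.5, s3 = 0.125))
  eff <- relative_quantities(make_cq(m, efficiency = c(g1 = 1.9, g2 = 2)))
  expect_equal(unname(eff["g1", "s3"]), 1.9^-3)
  expect_equal(unname(eff["g1", "s2"]), 1 / 1.9)
  # max quantity per gene is 1
  expect_equal(unname(apply(q, 1, max)), c(1, 1))
})

test_that("BestKeeper ranks by Cq dispersion", {
  m <- rbind(flat = c(20, 20, 20), seq3 = c(20, 21, 22), wide = c(18, 22, 26))
  colnames(m) <- paste0("s", 1:3)
  rep <- bestkeeper_stats(make_cq(m))
  expect_equal(rep$ranking$gene, c("flat", "seq3", "wide"))
  expect_equal(rep$ranking$statistic, c(0, 1, 4))
  expect_equal(rep$best_pair, c("flat", "seq3"))
  # MAD variant: mean |x - mean| of (20,21,22) is 2/3
  mad_rep <- bestkeeper_stats(make_cq(m), use_mad = TRUE)
  expect_equal(mad_rep$ranking$statistic[2], 2 / 3)
  expect_error(bestkeeper_stats(make_cq(m[, 1, drop = FALSE])), "2 samples")
})

test_that("geNorm reproduces hand-computed pairwise variabilities", {
  # log2 quantities g1 = g2 = (0,1,2,3), g3 constant
  m <- rbind(g1 = c(3, 2, 1, 0), g2 = c(5, 4, 3, 2), g3 = c(7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:4)
  rep <- genorm(make_cq(m))
  v13 <- sd(c(0, 1, 2, 3))                     # 1.29099...
  expect_equal(rep$trace[[1]][["g1"]], v13 / 2)
  expect_equal(rep$trace[[1]][["g2"]], v13 / 2)
  expect_equal(rep$trace[[1]][["g3"]], v13)
  expect_equal(rep$best_pair, c("g1", "g2"))
  # final two genes share an identical M (their mutual V)
  expect_equal(rep$trace[[2]][["g1"]], rep$trace[[2]][["g2"]])
  expect_equal(rep$trace[[2]][["g1"]], 0)
  expect_error(genorm(make_cq(m[1:2, ])), ">= 3")

  # M is invariant under per-gene constant Cq shifts
  shifted <- m + c(5, -2, 1)
  rep2 <- genorm(make_cq(shifted))
  expect_equal(rep2$ranking, rep$ranking)
})

test_that("NormFinder absorbs sample-wide shifts and flags noisy genes", {
  m <- rbind(g1 = c(20, 21, 22, 23), g2 = c(25, 26, 27, 28),
             g3 = c(30, 31, 32, 33))
  colnames(m) <- paste0("s", 1:4)
  rep <- normfinder(make_cq(m))
  expect_equal(rep$ranking$statistic, c(0, 0, 0))  # identical profiles

  set.seed(42)
  hits <- 0
  for (i in 1:20) {
    noisy <- m
    noisy["g2", ] <- noisy["g2", ] + rnorm(4, 0, 0.9)
    noisy["g1", ] <- noisy["g1", ] + rnorm(4, 0, 0.05)
    noisy["g3", ] <- noisy["g3", ] + rnorm(4, 0, 0.05)
    r <- normfinder(make_cq(noisy))
    if (r$ranking$gene[3] == "g2") hits <- hits + 1
    # loading-shift invariance: add a constant to one sample's Cq everywhere
    shifted <- noisy
    shifted[, 2] <- shifted[, 2] + 1.7
    expect_equal(normfinder(make_cq(shifted))$ranking, r$ranking)
  }
  expect_gte(hits, 19)

  # grouped mode falls back with a warning when only one condition exists
  expect_warning(normfinder(make_cq(m), grouped = TRUE), "falling back")
})

fake_report <- function(genes, best = sort(genes[1:2])) {
  structure(list(method = "fake",
                 ranking = data.frame(gene = genes,
                                      statistic = seq_along(genes),
                                      rank = seq_along(genes)),
                 statistic_name = "x", best_pair = best, trace = NULL),
            class = "stability_report")
}

test_that("consensus reference pair uses mean rank with deterministic ties", {
  agree <- list(fake_report(c("UB", "CDK", "ATUB", "BTUB", "GAPDH")),
                fake_report(c("CDK", "UB", "ATUB", "BTUB", "GAPDH")),
                fake_report(c("UB", "CDK", "GAPDH", "ATUB", "BTUB")))
  expect_equal(select_reference_pair(agree), c("CDK", "UB"))
  expect_equal(select_reference_pair(agree[1]), c("CDK", "UB"))
  conflict <- list(fake_report(c("A", "B", "C")), fake_report(c("C", "A", "B")))
  # mean ranks: A 1.5, B 2.5, C 2 -> pair {A, C}
  expect_equal(select_reference_pair(conflict), c("A", "C"))
  expect_error(select_reference_pair(list()), "at least one")
})

test_that("relative expression matches the E^ddCq closed forms", {
  m <- rbind(ref1 = rep(20, 6), ref2 = rep(22, 6),
             tgt = c(25, 25, 25, 22, 22, 22))
  colnames(m) <- paste0("s", 1:6)
  cond <- rep(c("control", "T"), each = 3)
  cq <- make_cq(m, roles = c("candidate_RG", "candidate_RG", "target"),
                conditions = cond)
  res <- suppressWarnings(
    rel_expression(cq, refs = c("ref1", "ref2")))
  expect_equal(res$ratio, 8, tolerance = 1e-12)
  expect_equal(res$log2_ratio, 3, tolerance = 1e-12)

  cq19 <- make_cq(m, roles = c("candidate_RG", "candidate_RG", "target"),
                  conditions = cond,
                  efficiency = c(ref1 = 2, ref2 = 2, tgt = 1.9))
  res19 <- suppressWarnings(rel_expression(cq19, refs = c("ref1", "ref2")))
  expect_equal(res19$ratio, 1.9^3, tolerance = 1e-12)
  expect_equal(res19$ratio, 6.859, tolerance = 1e-12)

  # zero variance in both groups flags p = 0 with a warning
  expect_warning(rel_expression(cq, refs = "ref1"), "zero replicate variance")

  # control vs control gives log2 ratio 0 everywhere
  mm <- m
  cond2 <- rep(c("control", "c2"), each = 3)
  mm["tgt", ] <- 25
  cq0 <- make_cq(mm, roles = c("candidate_RG", "candidate_RG", "target"),
                 conditions = cond2)
  r0 <- rel_expression(cq0, refs = c("ref1", "ref2"), conditions = "c2")
  expect_equal(r0$log2_ratio, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$significance, "ns")
})

test_that("t-test and permutation p-values agree with direct computation", {
  set.seed(5)
  cq <- simulate_cq_table(seed = 5)
  res <- rel_expression(cq, targets = "ALKBH10B", refs = c("CDK", "UB"),
                        conditions = "Zn10")
  # recompute the t-test by hand on reference-normalized log2 expression
  cond <- cq$sample_info$condition
  z <- -cq$cq["ALKBH10B", ] + (cq$cq["CDK", ] + cq$cq["UB", ]) / 2
  p_ref <- t.test(z[cond == "Zn10"], z[cond == "control"],
                  var.equal = TRUE)$p.value
  expect_equal(res$p_value, p_ref)
  expect_equal(res$significance, "***")

  perm <- rel_expression(cq, targets = "ALKBH10B", refs = c("CDK", "UB"),
                         conditions = "Zn10", method = "permutation",
                         n_perm = 500, seed = 9)
  # with 3 vs 3 replicates only 20 label splits exist, so the smallest
  # attainable permutation p is about 0.1
  expect_lt(perm$p_value, 0.15)
  expect_equal(perm$log2_ratio, res$log2_ratio)
  # permutation p is reproducible under the same seed
  perm2 <- rel_expression(cq, targets = "ALKBH10B", refs = c("CDK", "UB"),
                          conditions = "Zn10", method = "permutation",
                          n_perm = 500, seed = 9)
  expect_identical(perm, perm2)

  expect_error(rel_expression(cq, refs = "nope"), "absent")
  expect_error(rel_expression(cq, refs = "CDK", control_condition = "zzz"),
               "absent")
})

test_that("growth_rate recovers exponential slopes", {
  s <- simulate_growth(rate = 0.45, noise_cv = 0)
  expect_equal(growth_rate(s)$rate, 0.45, tolerance = 1e-12)
  expect_equal(growth_rate(s)$r_squared, 1)

  # two-point window reduces to ln(Nt/N0)/dt
  two <- data.frame(day = c(0, 7), density = c(5000, 5000 * exp(3.15)))
  expect_equal(growth_rate(two)$rate, 0.45, tolerance = 1e-12)

  flat <- data.frame(day = 0:5, density = rep(800, 6))
  expect_equal(growth_rate(flat)$rate, 0)

  expect_error(growth_rate(data.frame(day = 0:1, density = c(5, -1))),
               "positive")
  expect_error(growth_rate(data.frame(day = c(0, 0), density = c(5, 5))),
               "increasing")
  # window subsetting
  s2 <- simulate_growth(rate = 0.3, days = 0:10, noise_cv = 0)
  expect_equal(growth_rate(s2, window = c(2, 6))$n, 5)
  expect_equal(growth_rate(s2, window = c(2, 6))$rate, 0.3, tolerance = 1e-12)
})
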