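test_that("dataset correlations match direct Pearson computation and conventions", {
  m <- rbind(GLI1 = c(1, 2, 3),
             COPY = c(1, 2, 3),
             NEG  = c(3, 2, 1),
             MIX  = c(1, 3, 2))
  colnames(m) <- paste0("S", 1:3)
  prof <- dataset_correlations(make_dataset(m), targets = "GLI1")$GLI1
  expect_equal(prof$entries[["COPY"]], 1)
  expect_equal(prof$entries[["NEG"]], -1)
  expect_equal(prof$entries[["MIX"]], 0.5)   # cor(c(1,2,3), c(1,3,2))
  expect_equal(prof$entries[["GLI1"]], 1)    # self-correlation
  expect_false("ABSENT" %in% names(prof$entries))
})

test_that("absent or constant targets skip the dataset with a warning", {
  m <- rbind(GLI1 = c(5, 5, 5), OTHER = c(1, 2, 3))
  colnames(m) <- paste0("S", 1:3)
  w <- capture_warnings(res <- dataset_correlations(make_dataset(m),
                                                    targets = c("GLI1", "GLI2")))
  expect_length(w, 2)  # GLI1 constant, GLI2 absent
  expect_match(w, "absent or constant", all = TRUE)
  expect_length(res, 0)
})

test_that("coverage filter honours the inclusive min-types boundary", {
  presence <- list(A = paste0("T", 1:30), B = paste0("T", 1:29),
                   C = paste0("T", 1:37))
  expect_setequal(filter_genes_by_coverage(presence, 30), c("A", "C"))
  expect_setequal(filter_genes_by_coverage(presence, 1), c("A", "B", "C"))
})

test_that("profile averaging is a missing-aware unweighted mean", {
  p1 <- list(target = "GLI1", level = "dataset", cancer_type = "x",
             entries = c(GA = 0.2, GB = 0.7),
             n_contributing = c(GA = 1L, GB = 1L))
  p2 <- list(target = "GLI1", level = "dataset", cancer_type = "x",
             entries = c(GA = 0.4),
             n_contributing = c(GA = 1L))
  p3 <- list(target = "GLI1", level = "dataset", cancer_type = "y",
             entries = c(GA = 0.6),
             n_contributing = c(GA = 1L))
  avg <- average_profiles(list(p1, p2, p3))
  expect_equal(avg$entries[["GA"]], mean(c(0.2, 0.4, 0.6)))
  expect_equal(avg$entries[["GB"]], 0.7)         # only one contributor
  expect_equal(avg$n_contributing[["GB"]], 1L)

  by_type <- average_profiles(list(p1, p2, p3), "cancer_type")
  expect_equal(by_type$x$entries[["GA"]], 0.3)
  expect_equal(by_type$y$entries[["GA"]], 0.6)

  two_stage <- average_profiles(list(p1, p2, p3), two_stage = TRUE)
  expect_equal(two_stage$entries[["GA"]], mean(c(0.3, 0.6)))

  # averaging identical profiles reproduces any one of them
  same <- average_profiles(list(p1, p1, p1))
  expect_equal(same$entries, p1$entries)

  expect_error(average_profiles(list()), "empty")
  p_other <- p1; p_other$target <- "GLI2"
  expect_error(average_profiles(list(p1, p_other)), "mix targets")
})

test_that("average of correlations is bounded by the contributing values", {
  set.seed(4)
  for (i in 1:20) {
    rs <- runif(5, -1, 1)
    ps <- lapply(rs, function(r)
      list(target = "GLI1", level = "dataset", cancer_type = "x",
           entries = c(G = r), n_contributing = c(G = 1L)))
    avg <- average_profiles(ps)$entries[["G"]]
    expect_gte(avg, min(rs)); expect_lte(avg, max(rs))
  }
})

test_that("gene ranking uses decreasing-r mean-rank percentiles", {
  prof <- list(target = "GLI1", level = "pan_cancer",
               entries = setNames(seq(1, 0.01, length.out = 100),
                                  paste0("G", 1:100)))
  pct <- rank_genes(prof, c("G1", "G100"))
  expect_equal(pct[["G1"]], 1)      # top gene of 100
  expect_equal(pct[["G100"]], 100)

  # ties at ranks 2-3 of 10 share the mean-rank percentile 25
  r <- c(A = 0.9, B = 0.5, C = 0.5, setNames(seq(0.4, 0.1, length.out = 7),
                                             paste0("D", 1:7)))
  prof2 <- list(target = "GLI1", level = "pan_cancer", entries = r)
  pct2 <- rank_genes(prof2, c("B", "C"))
  expect_equal(unname(pct2), c(25, 25))

  # median gene of an odd-length list sits at ~50
  odd <- list(target = "GLI1", level = "pan_cancer",
              entries = setNames(seq(0.9, 0.1, length.out = 9), paste0("G", 1:9)))
  expect_equal(rank_genes(odd, "G5")[["G5"]], 100 * 5 / 9)

  expect_error(rank_genes(prof, "NOPE"), "absent")
})

test_that("percentiles are permutation-equivariant in the r values", {
  set.seed(6)
  r <- setNames(runif(20, -1, 1), paste0("G", 1:20))
  prof <- list(target = "GLI1", level = "pan_cancer", entries = r)
  perm <- sample(20)
  prof_p <- list(target = "GLI1", level = "pan_cancer", entries = r[perm])
  pct <- rank_genes(prof, names(r))
  pct_p <- rank_genes(prof_p, names(r))
  expect_equal(pct_p[names(r)], pct)
})

test_that("the focal matrix averages per-dataset correlations and calls r > 0.25 strictly", {
  R <- diag(8); dimnames(R) <- list(focal_genes(), focal_genes())
  R["GLI1", "GLI2"] <- R["GLI2", "GLI1"] <- 0.6
  set.seed(10)
  datasets <- lapply(1:3, function(i)
    list(expr = make_focal_dataset(500, R, id = paste0("D", i))))
  fm <- focal_matrix(datasets)
  expect_equal(fm$values, t(fm$values))
  expect_equal(unname(diag(fm$values)), rep(1, 8))
  expect_equal(fm$values["GLI1", "GLI2"], 0.6, tolerance = 0.06 / 0.6)
  expect_true(fm$positive["GLI1", "GLI2"])
  expect_equal(unname(fm$n_contributing["GLI1", "GLI2"]), 3L)

  # a dataset missing SHH still contributes the remaining pairs
  d4 <- make_focal_dataset(100, R, id = "D4")
  d4$values <- d4$values[setdiff(rownames(d4$values), "SHH"), ]
  fm2 <- focal_matrix(c(datasets, list(list(expr = d4))))
  expect_equal(unname(fm2$n_contributing["GLI1", "GLI2"]), 4L)
  expect_equal(unname(fm2$n_contributing["GLI1", "SHH"]), 3L)
})

test_that("an averaged r of exactly 0.25 is not called positive", {
  # two synthetic two-gene datasets engineered to average to exactly 0.25
  base <- c(1, 2, 3, 4)
  make_pair_with_r <- function(r, id) {
    # second gene = r * z(base) + sqrt(1-r^2) * orthogonal unit vector
    zb <- (base - mean(base)) / sd(base)
    orth <- c(1, -1, -1, 1); orth <- (orth - mean(orth)) / sd(orth)
    m <- rbind(GLI1 = zb, GLI2 = r * zb + sqrt(1 - r^2) * orth)
    colnames(m) <- paste0("S", 1:4)
    list(expr = make_dataset(m, id = id))
  }
  ds <- list(make_pair_with_r(0.3, "A"), make_pair_with_r(0.2, "B"))
  fm <- focal_matrix(ds)
  expect_equal(fm$values["GLI1", "GLI2"], 0.25, tolerance = 1e-12)
  # strictness: an average exactly at the threshold is NOT called positive
  fm_b <- focal_matrix(ds, threshold = fm$values["GLI1", "GLI2"])
  expect_false(fm_b$positive["GLI1", "GLI2"])
  fm_c <- focal_matrix(ds, threshold = fm$values["GLI1", "GLI2"] - 1e-9)
  expect_true(fm_c$positive["GLI1", "GLI2"])
})

test_that("with identity correlation, positive calls vanish as n grows", {
  set.seed(12)
  datasets <- lapply(1:4, function(i)
    list(expr = make_focal_dataset(300, diag(8), id = paste0("D", i))))
  fm <- focal_matrix(datasets)
  off <- fm$positive[upper.tri(fm$positive)]
  expect_lte(mean(off), 0.05)
})
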