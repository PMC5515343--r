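mt <- function(m, kind = "beta") {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("cg%03d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
  matrix_table(m, kind)
}

test_that("differential probe selection recovers constructed extremes", {
  n <- 1000
  tumor <- matrix(0.5, n, 4)
  normal <- matrix(0.5, n, 4)
  tumor[1:500, ] <- 0.8    # diff +0.3
  normal[501:1000, ] <- 0.8  # diff -0.3
  ids <- sprintf("cg%04d", seq_len(n))
  rownames(tumor) <- rownames(normal) <- ids
  colnames(tumor) <- colnames(normal) <- paste0("s", 1:4)
  ps <- select_differential_probes(mt(tumor), mt(normal))
  expect_setequal(ps$hyper_probes, ids[1:500])
  expect_setequal(ps$hypo_probes, ids[501:1000])
})

test_that("identical tumor and normal matrices cannot yield signed probes", {
  m <- mt(matrix(runif(1200 * 3), 1200, 3))
  expect_error(select_differential_probes(m, m), "not enough signed")
})

test_that("probe selection equals a full-sort oracle on random matrices", {
  set.seed(31)
  for (rep in 1:3) {
    tumor <- mt(matrix(runif(300 * 5), 300, 5))
    normal <- mt(matrix(runif(300 * 5), 300, 5))
    ps <- select_differential_probes(tumor, normal, n_hyper = 50, n_hypo = 50)
    d <- rowMeans(tumor) - rowMeans(normal)
    ord <- order(-d, names(d))
    expect_equal(ps$hyper_probes, names(d)[ord][1:50])
    ord_lo <- order(d, names(d))
    expect_equal(ps$hypo_probes, names(d)[ord_lo][1:50])
  }
})

test_that("occult regression matches closed forms and the OLS oracle", {
  probes <- list(hyper_probes = sprintf("cg%03d", 1:50))
  x <- seq(0.2, 0.9, length.out = 50)
  names(x) <- probes$hyper_probes
  fit <- fit_occult_regression(x, x, probes)
  expect_equal(fit$slope, 1)
  expect_equal(fit$residual_se, 0, tolerance = 1e-12)

  y <- 0.5 * x + 0.1
  fit <- fit_occult_regression(y, x, probes)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$residual_se, 0, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:5) {
    y <- pmin(1, pmax(0, 0.6 * x + rnorm(50, 0, 0.05)))
    names(y) <- names(x)
    fit <- fit_occult_regression(y, x, probes)
    orc <- oracle_ols(x, y)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$residual_se, orc$residual_se, tolerance = 1e-10)
    expect_equal(fit$n_probes, 50)
  }
})

test_that("regression guards degenerate inputs", {
  probes <- list(hyper_probes = sprintf("cg%03d", 1:50))
  x <- rep(0.5, 50); names(x) <- probes$hyper_probes
  expect_error(fit_occult_regression(x, x, probes), "zero variance")
  probes_small <- list(hyper_probes = sprintf("cg%03d", 1:5))
  expect_error(fit_occult_regression(x[1:5], seq(0, 1, length.out = 5),
                                     probes_small), "fewer than 10")
})

test_that("classification applies strict slope and rse thresholds", {
  mk <- function(slope, rse) structure(list(slope = slope, intercept = 0,
                                            residual_se = rse, n_probes = 500,
                                            category = NA_character_),
                                       class = "occult_fit")
  expect_equal(classify_methylation(mk(0.6, 0.5))$category, "occult_tumor")
  expect_equal(classify_methylation(mk(0.6, 1.5))$category, "field_effect")
  expect_equal(classify_methylation(mk(0.4, 0.0))$category, "normal")
  expect_equal(classify_methylation(mk(0.41, 1.0))$category, "field_effect")
  expect_equal(classify_methylation(mk(-0.2, 0.1))$category, "normal")
  # configurable thresholds
  expect_equal(classify_methylation(mk(0.3, 0.1), slope_threshold = 0.2)$category,
               "occult_tumor")
})

test_that("classification is scale-free in probe count", {
  probes <- list(hyper_probes = sprintf("cg%03d", 1:40))
  set.seed(4)
  x <- runif(40, 0.2, 0.9); names(x) <- probes$hyper_probes
  y <- pmin(1, 0.7 * x + rnorm(40, 0, 0.03)); names(y) <- names(x)
  f1 <- classify_methylation(fit_occult_regression(y, x, probes))
  dbl <- list(hyper_probes = sprintf("cg%03d", c(1:40, 1:40)))
  f2 <- classify_methylation(fit_occult_regression(y, x, dbl))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$category, f1$category)
})

test_that("sample ranking follows slope desc, rse asc, then id", {
  mk <- function(id, slope, rse) structure(
    list(sample_id = id, slope = slope, intercept = 0, residual_se = rse,
         n_probes = 500, category = "normal"), class = "occult_fit")
  res <- rank_samples(list(mk("a", 0.2, 0.1), mk("b", 0.9, 0.5),
                           mk("c", 0.9, 0.2), mk("d", 0.2, 0.1)))
  expect_equal(res$sample_id, c("c", "b", "a", "d"))

  set.seed(12)
  fits <- lapply(1:30, function(i)
    mk(sprintf("s%02d", i), sample(c(0.2, 0.5, 0.8), 1),
       sample(c(0.1, 0.3), 1)))
  got <- rank_samples(fits)
  ids <- vapply(fits, function(f) f$sample_id, character(1))
  key <- order(-vapply(fits, function(f) f$slope, numeric(1)),
               vapply(fits, function(f) f$residual_se, numeric(1)),
               ids)
  expect_equal(got$sample_id, ids[key])
})

test_that("cellularity confound check reproduces exact correlations", {
  set.seed(6)
  m <- mt(matrix(runif(600 * 10), 600, 10))
  probes <- list(hyper_probes = rownames(m)[1:100])
  med <- apply(unclass(m)[1:100, ], 2, median)
  r1 <- cellularity_confound_check(m, probes, med)
  expect_equal(r1$pearson_r, 1, tolerance = 1e-12)
  neg <- -med; names(neg) <- names(med)
  r2 <- cellularity_confound_check(m, probes, neg)
  expect_equal(r2$pearson_r, -1, tolerance = 1e-12)
  expect_error(cellularity_confound_check(
    m, probes, setNames(rep(0.5, 10), colnames(m))), "constant")
})

test_that("independent cellularity shows no correlation on average", {
  set.seed(19)
  rs <- replicate(200, {
    med <- runif(40)
    cellu <- setNames(runif(40), paste0("s", 1:40))
    names(med) <- names(cellu)
    cor(med, cellu)
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(abs(mean(abs(rs)) - 0.13), 0.04)
})
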