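test_that("the CARS retention schedule follows the exponential decay to 2", {
  pi_ <- planted_instance(seed = 21)
  res <- cars(pi_$X, pi_$y, n_runs = 30, max_factors = 5, seed = 1)
  sched <- res$diagnostics$n_retained
  expect_true(all(diff(sched) <= 0))
  expect_equal(sched[length(sched)], 2L)
  # closed-form EDF oracle, within ceiling effects and the running minimum
  p <- ncol(pi_$X); n_runs <- 30
  kk <- log(p / 2) / (n_runs - 1); a <- exp(kk)
  edf <- pmax(2, pmin(cummin(ceiling(a * exp(-kk * seq_len(n_runs)) * p)), p))
  expect_equal(sched, cummin(pmin(edf, c(p, sched[-n_runs]))))
  # two runs collapse straight to the boundary count
  res2 <- cars(pi_$X, pi_$y, n_runs = 2, max_factors = 5, seed = 1)
  expect_equal(res2$diagnostics$n_retained[2], 2L)
})

test_that("CARS is deterministic given a seed and finds planted variables", {
  pi_ <- planted_instance(seed = 22)
  a <- cars(pi_$X, pi_$y, n_runs = 40, max_factors = 5, seed = 9)
  b <- cars(pi_$X, pi_$y, n_runs = 40, max_factors = 5, seed = 9)
  expect_identical(a$selected, b$selected)
  expect_true(all(pi_$informative %in% a$selected))
  expect_error(cars(pi_$X[, 1, drop = FALSE], pi_$y, seed = 1),
               "at least 2")
})

test_that("selectivity ratio scores behave as a target-projection variance ratio", {
  set.seed(23)
  n <- 40
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 8), n, 8))  # first column IS the response
  res <- selectivity_ratio(X, y, 3)
  expect_equal(which.max(res$scores), 1L)
  expect_true(1 %in% res$selected)
  # scale invariance in y
  res10 <- selectivity_ratio(X, 10 * y, 3)
  expect_equal(res$scores, res10$scores, tolerance = 1e-8)
  # a variable orthogonal to the regression vector scores ~0
  set.seed(24)
  X2 <- matrix(rnorm(60 * 5), 60, 5)
  y2 <- X2[, 1]
  orth <- residuals(lm(rnorm(60) ~ X2[, 1]))
  res2 <- selectivity_ratio(cbind(X2[, 1], orth), y2, 1)
  expect_lt(res2$scores[2], 0.2)
  expect_false(2 %in% res2$selected)
  # threshold is the stated F critical value
  expect_equal(res$threshold, qf(0.95, n - 2, n - 3), tolerance = 1e-12)
})

test_that("VIP satisfies its analytic identity and ranks planted variables first", {
  set.seed(25)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 12), 30, 12)
    y <- as.vector(X %*% rnorm(12)) + rnorm(30, 0.3)
    res <- vip(X, y, 4)
    expect_equal(mean(res$scores^2), 1, tolerance = 1e-10)
  }
  # identical informative columns share VIP 1 by symmetry
  set.seed(26)
  base <- rnorm(40)
  Xeq <- matrix(rep(base, 6), 40, 6)
  yeq <- base + rnorm(40, 0, 0.1)
  req <- vip(Xeq, yeq, 1)
  expect_equal(req$scores, rep(1, 6), tolerance = 1e-10)
  # planted signal carries the top-3 VIP
  pi_ <- planted_instance(seed = 27)
  rp <- vip(pi_$X, pi_$y, 3)
  expect_setequal(order(rp$scores, decreasing = TRUE)[1:3], pi_$informative)
  expect_true(all(pi_$informative %in% rp$selected))
})

test_that("UVE always keeps a planted strong signal and is deterministic", {
  pi_ <- planted_instance(seed = 28)
  a <- uve(pi_$X, pi_$y, 5, seed = 3)
  b <- uve(pi_$X, pi_$y, 5, seed = 3)
  expect_identical(a$selected, b$selected)
  expect_true(all(pi_$informative %in% a$selected))
  # the cutoff is the maximum absolute noise stability by default
  expect_equal(a$threshold, max(abs(a$diagnostics$noise_stability)),
               tolerance = 1e-12)
})

test_that("UVE selects almost nothing under a pure-noise null", {
  set.seed(29)
  frac <- vapply(1:20, function(r) {
    X <- matrix(rnorm(60 * 200), 60, 200)
    y <- rnorm(60)
    length(uve(X, y, 3, seed = r)$selected) / 200
  }, numeric(1))
  expect_true(all(frac <= 0.05))
})

test_that("MC-UVE stabilities track UVE's on near-LOO subsets", {
  pi_ <- planted_instance(n = 50, seed = 30)
  u <- uve(pi_$X, pi_$y, 5, seed = 4)
  m <- mc_uve(pi_$X, pi_$y, 5, n_models = 50, sample_ratio = 49 / 50,
              seed = 4)
  expect_gt(cor(u$scores, m$scores), 0.9)
  expect_true(all(pi_$informative %in% m$selected))
  m2 <- mc_uve(pi_$X, pi_$y, 5, n_models = 50, sample_ratio = 49 / 50,
               seed = 4)
  expect_identical(m$selected, m2$selected)
})

test_that("refitting on any method's selection keeps calibration error competitive", {
  # informative-variable retention: restricting to the selected subset never
  # degrades RMSEC by more than 20% on a planted-signal instance; n is kept
  # large relative to the factor count so the full-spectrum RMSEC is not an
  # overfit floor
  pi_ <- planted_instance(n = 150, noise_sd = 0.05, seed = 31)
  full <- fit_pls(pi_$X, pi_$y, 5)
  rmsec_full <- sqrt(mean((predict(full, pi_$X) - pi_$y)^2))
  sels <- list(
    cars(pi_$X, pi_$y, n_runs = 40, max_factors = 5, seed = 5),
    selectivity_ratio(pi_$X, pi_$y, 5),
    vip(pi_$X, pi_$y, 5),
    uve(pi_$X, pi_$y, 5, seed = 5),
    mc_uve(pi_$X, pi_$y, 5, n_models = 100, seed = 5))
  for (s in sels) {
    vars <- s$selected
    if (length(vars) < 2) next
    f <- fit_pls(pi_$X[, vars, drop = FALSE], pi_$y,
                 min(5, length(vars)))
    rmsec <- sqrt(mean((predict(f, pi_$X[, vars, drop = FALSE]) - pi_$y)^2))
    expect_lt(rmsec, 1.2 * rmsec_full)
  }
})

test_that("CARS is more parsimonious than VIP on spectra-like data", {
  # the reproducible slice of the method-ordering tendency: the CV-optimal
  # CARS subset is far smaller than the VIP>1 set on band-structured spectra
  ds <- cached_synthetic(seed = 1)
  sp <- preprocess(ds$spectra)
  ok <- 0
  for (s in 1:3) {
    part <- make_partition(sp, ds$reference, "soluble_sugar")
    Xc <- sp$absorbance[part$calibration, ]
    yc <- ds$reference$soluble_sugar[part$calibration]
    ca <- cars(Xc, yc, max_factors = 10, seed = s)
    v <- vip(Xc, yc, 6)
    if (length(ca$selected) < length(v$selected)) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("consensus categorization partitions the variables", {
  p <- 40
  mk <- function(method, sel) selection_result_for_test(method, p, sel)
  # helper below builds a minimal selection_result-compatible object
  all_sel <- lapply(c("CARS", "SR", "VIP", "UVE", "MC_UVE"),
                    function(m) mk(m, seq_len(p)))
  cm <- categorize_consensus(all_sel, p)
  expect_equal(cm$summary$n[cm$summary$class == "MIV"], p)
  expect_equal(sum(cm$summary$n), p)
  expect_equal(sum(cm$summary$pct), 100, tolerance = 0.3)
  # duplicate methods are rejected
  expect_error(categorize_consensus(c(all_sel[1], all_sel[1], all_sel[3:5]),
                                    p), "distinct")
  expect_error(categorize_consensus(all_sel[1:3], p), "five")
})
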