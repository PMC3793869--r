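test_that("compound-symmetric covariance gives epsilon 1", {
  S <- matrix(0.4, 4, 4); diag(S) <- 1
  X <- .dataWithCov(12, S)
  expect_equal(ggEpsilon(X), 1, tolerance = 1e-12)
})

test_that("rank-one covariance gives the lower bound 1/3", {
  v <- c(1, 2, -1, 0.5)
  z <- rnorm(10)
  X <- outer(z, v)
  expect_equal(ggEpsilon(X), 1 / 3, tolerance = 1e-12)
})

test_that("epsilon matches the independent eigenvalue-route oracle", {
  set.seed(11)
  X <- matrix(rnorm(32, sd = rep(c(1, 2, 3, 0.5), each = 8)), 8, 4)
  expect_equal(ggEpsilon(X), ggEpsOracle(X), tolerance = 1e-10)
  for (i in 1:20) {
    Y <- matrix(rnorm(40), 10, 4) + outer(rnorm(10), rep(1, 4))
    e <- ggEpsilon(Y)
    expect_equal(e, max(1 / 3, min(1, ggEpsOracle(Y))), tolerance = 1e-10)
    expect_gte(e, 1 / 3)
    expect_lte(e, 1)
  }
})

test_that("epsilon agrees with car's Greenhouse-Geisser estimate", {
  skip_if_not_installed("car")
  set.seed(19)
  X <- matrix(rnorm(60), 15, 4)
  colnames(X) <- domainLabels()
  fit <- stats::lm(X ~ 1)
  idata <- data.frame(domain = factor(domainLabels(),
                                      levels = domainLabels()))
  av <- car::Anova(fit, idata = idata, idesign = ~domain, type = 3)
  s <- summary(av, multivariate = FALSE)
  carEps <- s$pval.adjustments[1, "GG eps"]
  expect_equal(ggEpsilon(X), unname(carEps), tolerance = 1e-8)
})

test_that("constant data give epsilon 1 with a degeneracy flag", {
  X <- matrix(5, 6, 4) + rnorm(6)   # column-constant after centering rows?
  X <- matrix(5, 6, 4)
  e <- ggEpsilon(X)
  expect_equal(as.numeric(e), 1)
  expect_true(isTRUE(attr(e, "degenerate")))
})

test_that("identical domain values give F = 0 and p = 1", {
  X <- matrix(rep(rnorm(8), 4), 8, 4)   # per-cell constant across domains
  colnames(X) <- domainLabels()
  res <- rmAnovaGG(X)
  expect_equal(res@F, 0)
  expect_equal(res@pGG, 1)
})

test_that("F statistic and uncorrected p match aov's within-subject ANOVA", {
  set.seed(23)
  X <- matrix(rnorm(48, mean = rep(c(0, 0.5, 0, 0), each = 12)), 12, 4)
  colnames(X) <- domainLabels()
  res <- rmAnovaGG(X)
  long <- data.frame(y = as.vector(X),
                     subj = factor(rep(1:12, 4)),
                     dom = factor(rep(domainLabels(), each = 12)))
  fit <- summary(stats::aov(y ~ dom + Error(subj / dom), data = long))
  tab <- fit[["Error: subj:dom"]][[1]]
  expect_equal(res@F, tab["dom", "F value"], tolerance = 1e-10)
  expect_equal(res@pUncorrected, tab["dom", "Pr(>F)"], tolerance = 1e-10)
})

test_that("sphericity-true data leave the corrected p equal to the classical p", {
  S <- diag(4) * 0.5 + 0.3
  X <- .dataWithCov(14, S, seed = 3) + outer(rep(0, 14), c(0, 0.2, 0, 0.1))
  colnames(X) <- domainLabels()
  res <- rmAnovaGG(X)
  expect_equal(res@epsilon, 1, tolerance = 1e-10)
  expect_equal(res@pGG, res@pUncorrected, tolerance = 1e-10)
})

test_that("the correction is conservative wherever the test can reject", {
  set.seed(31)
  for (i in 1:25) {
    X <- matrix(rnorm(40, mean = rep(runif(4, 0, 0.5), each = 10),
                      sd = rep(runif(4, 0.5, 2), each = 10)), 10, 4)
    colnames(X) <- domainLabels()
    res <- rmAnovaGG(X)
    if (res@F >= 2) expect_gte(res@pGG, res@pUncorrected - 1e-12)
    expect_gte(res@epsilon, 1 / 3)
    expect_lte(res@epsilon, 1)
    expect_equal(res@pairwise$p_bonferroni,
                 pmin(1, 6 * res@pairwise$p_raw))
  }
})

test_that("p_GG increases monotonically as epsilon decreases", {
  Fv <- 3.2; n <- 20
  eps <- seq(1, 1 / 3, length.out = 9)
  p <- stats::pf(Fv, 3 * eps, 3 * (n - 1) * eps, lower.tail = FALSE)
  expect_true(all(diff(p) > 0))
})

test_that("star levels map the conventional thresholds", {
  p <- CortexQuant:::.stars(c(0.0005, 0.005, 0.03, 0.2))
  expect_equal(p, c("***", "**", "*", "ns"))
})

test_that("pure-statistics type-I error is near nominal", {
  set.seed(41)
  rej <- 0L
  for (r in 1:400) {
    X <- matrix(rnorm(120), 30, 4)
    colnames(X) <- domainLabels()
    rej <- rej + (rmAnovaGG(X)@pGG < 0.05)
  }
  expect_gte(rej / 400, 0.02)
  expect_lte(rej / 400, 0.08)
})

test_that("stratification reproduces the distance bins", {
  meas <- data.frame(cell_id = rep(sprintf("c%d", 1:4), each = 4),
                     domain = rep(domainLabels(), 4),
                     ratio = rnorm(16, 1, 0.05))
  ann <- data.frame(cell_id = sprintf("c%d", 1:4),
                    class = "bipolar", tissue = "somite",
                    distance = c(1, 2, 3, 5))
  g <- stratify(meas, ann, scheme = "distance_bin")
  expect_setequal(names(g), c("<=2", "3-4", ">=5"))
  expect_equal(g[["<=2"]]$n, 2L)
  expect_equal(g[["3-4"]]$n, 1L)
  expect_equal(g[[">=5"]]$n, 1L)
  # single stratum when all cells share class and near distance
  ann2 <- ann; ann2$distance <- 1
  g2 <- stratify(meas, ann2, scheme = "class")
  expect_equal(names(g2), "bipolar")
  expect_equal(g2$bipolar$n, 4L)
  # shuffled annotations give identical groups
  g3 <- stratify(meas, ann[sample(4), ], scheme = "distance_bin")
  expect_equal(lapply(g3, `[[`, "values")[names(g)],
               lapply(g, `[[`, "values"))
  expect_error(stratify(rbind(meas,
    data.frame(cell_id = "zz", domain = "NSB", ratio = 1)), ann),
    "without annotation")
})

test_that("group summaries star planted effects and skip tiny groups", {
  set.seed(43)
  null1 <- matrix(rnorm(120, 1, 0.05), 30, 4)
  eff <- null1; eff[, 1] <- eff[, 1] + 0.3
  colnames(null1) <- colnames(eff) <- domainLabels()
  groups <- list(null = list(label = "null", values = null1, n = 30L),
                 eff = list(label = "eff", values = eff, n = 30L),
                 tiny = list(label = "tiny",
                             values = matrix(1, 1, 4,
                               dimnames = list("c", domainLabels())),
                             n = 1L))
  expect_message(figs <- summariseFigures(groups), "n < 3")
  expect_null(figs$tests$tiny)
  expect_lt(figs$tests$eff@pGG, 0.001)
  pw <- figs$pairwise
  nsbRows <- pw$group == "eff" & pw$domain_a == "NSB"
  expect_true(all(pw$stars[nsbRows] != "ns"))
  nullRows <- pw$group == "null"
  expect_true(all(pw$stars[nullRows] == "ns"))
  expect_equal(nrow(figs$summary), 12L)
})
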