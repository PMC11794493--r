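# Outlier exclusion, paired t, Greenhouse-Geisser epsilon, the
# repeated-measures ANOVA (checked against car::Anova as an independent
# oracle), and the simple-effects contract.

test_that("single-pass outlier exclusion removes only extreme points", {
  v <- c(1:10, 1000)
  # mean 95.91, sd 300.00: only 1000 lies beyond 3 SD
  res <- excludeOutliers(v, 3)
  expect_identical(res$removed, 11L)
  expect_identical(res$values, as.numeric(1:10))

  expect_identical(excludeOutliers(rep(5, 6))$removed, integer(0))
  expect_identical(excludeOutliers(v, Inf)$values, v)
})

test_that("paired t: hand oracle, identities, degenerate cases", {
  res <- pairedT(c(1, 2, 3), c(2, 4, 3))
  expect_equal(res$t, -sqrt(3), tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$cohens_dz, -1)

  # antisymmetry
  rev <- pairedT(c(2, 4, 3), c(1, 2, 3))
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)

  # agrees with one-sample t on differences
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10)
  one <- t.test(x - y)
  expect_equal(pairedT(x, y)$t, unname(one$statistic), tolerance = 1e-12)
  expect_equal(pairedT(x, y)$p, one$p.value, tolerance = 1e-12)

  same <- pairedT(1:5, 1:5)
  expect_identical(c(same$t, same$p), c(0, 1))
  degen <- pairedT(2:6, 1:5)
  expect_true(is.infinite(degen$t) && degen$p == 0)
  expect_error(pairedT(1, 1), "2 pairs")
})

test_that("GG epsilon: sphericity, bounds, eigenvalue oracle", {
  CS <- matrix(0.3, 4, 4); diag(CS) <- 1
  expect_equal(ggEpsilon(CS), 1)

  set.seed(6)
  for (r in 1:20) {
    k <- sample(3:5, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A)
    eps <- ggEpsilon(S)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1)
  }

  # fixed 3x3 covariance vs independent eigen evaluation
  S <- matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3, 3)
  M <- qr.Q(qr(cbind(rep(1, 3), diag(3))))[, 2:3]
  lam <- eigen(t(M) %*% S %*% M)$values
  expect_equal(ggEpsilon(S), sum(lam)^2 / (2 * sum(lam^2)), tolerance = 1e-12)

  expect_error(ggEpsilon(matrix(0, 3, 3)), "undefined")
})

test_that("RM-ANOVA: null-effect data, location invariance, completeness check", {
  subj <- rep(1:5, each = 6)
  grid <- expand.grid(channelType = c("a", "b", "c"),
                      musicType = c("x", "y"))
  tab <- data.frame(subject = subj,
                    channelType = grid$channelType[rep(1:6, 5)],
                    musicType = grid$musicType[rep(1:6, 5)],
                    value = rep(c(3, 7, 1, 9, 5), each = 6))
  res <- rmAnova(tab)
  expect_equal(res$SS, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$F, rep(0, 3), tolerance = 1e-12)

  set.seed(13)
  tab$value <- rnorm(nrow(tab))
  r1 <- rmAnova(tab)
  tab2 <- tab; tab2$value <- tab$value + 100
  r2 <- rmAnova(tab2)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p_gg, r2$p_gg, tolerance = 1e-9)
  expect_equal(r1$eta2p, r2$eta2p, tolerance = 1e-9)

  expect_error(rmAnova(tab[-1, ]), "incomplete")
})

test_that("RM-ANOVA F equals t^2 of the paired t on a 2-level factor", {
  set.seed(21)
  n <- 12
  tab <- data.frame(
    subject = rep(1:n, each = 2),
    channelType = "auditory",
    musicType = rep(c("nostalgic", "non-nostalgic"), n),
    value = rnorm(2 * n, mean = rep(c(5, 4), n))
  )
  # collapse the single-level factor: test musicType only via a 1 x 2 design
  fit <- rmAnova(tab, factorA = "musicType", factorB = "channelType")
  x <- tab$value[tab$musicType == "nostalgic"]
  y <- tab$value[tab$musicType == "non-nostalgic"]
  tt <- pairedT(x, y)
  i <- match("musicType", fit$effect)
  expect_equal(fit$F[i], tt$t^2, tolerance = 1e-9)
  expect_equal(fit$p[i], tt$p, tolerance = 1e-9)
})

test_that("RM-ANOVA matches car::Anova (SS, F, GG epsilon, corrected p)", {
  skip_if_not_installed("car")
  set.seed(33)
  b <- generateBehavior(simConfig(nSubjects = 12, seed = 33))
  tab <- cellMeans(b, "nostalgia")
  mine <- rmAnova(tab)

  cells <- expand.grid(musicType = sort(unique(tab$musicType)),
                       channelType = sort(unique(tab$channelType)))
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sub <- tab[tab$channelType == cells$channelType[i] &
               tab$musicType == cells$musicType[i], ]
    sub$value[order(sub$subject)]
  })
  idata <- data.frame(channelType = factor(cells$channelType),
                      musicType = factor(cells$musicType))
  av <- car::Anova(lm(Y ~ 1), idata = idata,
                   idesign = ~ channelType * musicType, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  for (eff in c("channelType", "musicType", "channelType:musicType")) {
    i <- match(eff, mine$effect)
    expect_equal(mine$SS[i], ut[eff, "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$F[i], ut[eff, "F value"], tolerance = 1e-9)
    expect_equal(mine$p[i], ut[eff, "Pr(>F)"], tolerance = 1e-9)
  }
  pa <- s$pval.adjustments
  expect_equal(mine$gg_epsilon[match("channelType", mine$effect)],
               pa["channelType", "GG eps"], tolerance = 1e-9)
  expect_equal(mine$p_gg[match("channelType", mine$effect)],
               pa["channelType", "Pr(>F[GG])"], tolerance = 1e-9)
})

test_that("hand-worked 2x2 toy ANOVA is reproduced exactly", {
  # 3 subjects, 2x2 within design; cell values chosen for clean arithmetic.
  #        A1B1 A1B2 A2B1 A2B2
  # s1:      2    4    6    8      (A effect 4, B effect 2, no interaction)
  # s2:      3    5    7    9
  # s3:      4    6    8   10
  # Effects are identical across subjects, so all error SS are exactly 0
  # except none -- F is infinite; instead perturb s3's A2B2 by +1:
  tab <- expand.grid(subject = 1:3, channelType = c("A1", "A2"),
                     musicType = c("B1", "B2"))
  vals <- c(2, 3, 4, 6, 7, 8,   # B1: A1 then A2
            4, 5, 6, 8, 9, 11)  # B2: A1 then A2 (s3 A2B2 = 11)
  tab$value <- vals
  res <- rmAnova(tab)
  # hand computation:
  # grand mean = 74/12; subject means: 5, 6, 7.25
  # A means: A1 = 4, A2 = 8.25 -> SS_A = 6*(4-6.125)^2*... computed directly:
  cellm <- with(tab, tapply(value, list(channelType, musicType), mean))
  am <- rowMeans(cellm); bm <- colMeans(cellm); gm <- mean(vals)
  SS_A <- 6 * sum((am - gm)^2)
  SS_B <- 6 * sum((bm - gm)^2)
  SS_AB <- 3 * sum((cellm - outer(am - gm, bm - gm, `+`) - gm)^2)
  expect_equal(res$SS[match("channelType", res$effect)], SS_A, tolerance = 1e-9)
  expect_equal(res$SS[match("musicType", res$effect)], SS_B, tolerance = 1e-9)
  expect_equal(res$SS[match("channelType:musicType", res$effect)], SS_AB,
               tolerance = 1e-9)
  # 2-level effects: GG epsilon is exactly 1
  expect_equal(res$gg_epsilon, rep(1, 3))
  expect_true(all(res$p_gg >= res$p - 1e-12))
})

test_that("simple effects reduce to paired t and flag the adjustment used", {
  set.seed(44)
  b <- generateBehavior(simConfig(nSubjects = 10, seed = 44))
  tab <- cellMeans(b, "nostalgia")
  se <- simpleEffects(tab, factor = "musicType", within = "channelType")
  # the 2-level factor's simple effect must equal pairedT exactly
  for (ct in unique(tab$channelType)) {
    sub <- tab[tab$channelType == ct, ]
    x <- sub$value[sub$musicType == se$level_1[se$at == ct][1]]
    y <- sub$value[sub$musicType == se$level_2[se$at == ct][1]]
    expect_equal(se$t[se$at == ct], pairedT(x, y)$t, tolerance = 1e-12)
  }
  expect_true(all(se$adjust == "none"))
  expect_equal(se$p_adjusted, se$p)

  seH <- simpleEffects(tab, factor = "channelType", within = "musicType",
                       adjust = "holm")
  expect_true(all(seH$p_adjusted >= seH$p - 1e-15))

  # identical cell values at one level -> t = 0
  tab0 <- tab
  tab0$value[tab0$musicType == "nostalgic"] <- 5
  se0 <- simpleEffects(tab0, factor = "channelType", within = "musicType")
  expect_equal(se0$t[se0$at == "nostalgic"], rep(0, 3))
})
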